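#' Responsive-gene ratios for one (condition, sex) contrast
#'
#' The core summary of sex dependency: for one perturbation contrast, each
#' sex-biased gene class is intersected with the up- and down-regulated
#' gene sets and the overlap counts are divided by the class totals,
#' giving four ratios, e.g.
#' `r_up_male_biased = |up & male_biased| / |male_biased|`.
#'
#' @param bias A `"SexBiasTable"` from [call_sex_bias()] (or
#'   [sex_bias_table()]).
#' @param perturb A `"PerturbationTable"` from [call_perturbation()] (or
#'   [perturbation_table()]) over the same gene universe.
#' @return A `"ResponsiveRatios"`: list with `condition`, `time_point`,
#'   `sex`, `ratios` (named numeric: `r_up_male_biased`,
#'   `r_down_male_biased`, `r_up_female_biased`, `r_down_female_biased`)
#'   and `counts` (the eight underlying integers: four overlap counts plus
#'   `n_male_biased`, `n_female_biased`, `n_up`, `n_down`).
#' @details An empty male-biased or female-biased class makes the ratios
#'   undefined and is an error, never a silent `0/0`.
#' @export
responsive_ratios <- function(bias, perturb) {
  if (!inherits(bias, "SexBiasTable"))
    stop("`bias` must be a SexBiasTable", call. = FALSE)
  if (!inherits(perturb, "PerturbationTable"))
    stop("`perturb` must be a PerturbationTable", call. = FALSE)
  bg <- bias$gene_id
  if (length(bg) != nrow(perturb) || !setequal(bg, perturb$gene_id))
    stop("bias and perturbation tables cover different gene universes",
         call. = FALSE)
  reg <- perturb$regulation[match(bg, perturb$gene_id)]
  cls <- bias$class
  mb <- cls == "male_biased"
  fb <- cls == "female_biased"
  n_mb <- sum(mb)
  n_fb <- sum(fb)
  if (n_mb == 0L || n_fb == 0L)
    stop("undefined ratios: ",
         if (n_mb == 0L) "no male-biased genes" else "no female-biased genes",
         " in the bias table", call. = FALSE)
  up <- reg == "up"
  down <- reg == "down"
  counts <- c(up_male_biased = sum(mb & up),
              down_male_biased = sum(mb & down),
              up_female_biased = sum(fb & up),
              down_female_biased = sum(fb & down),
              n_male_biased = n_mb, n_female_biased = n_fb,
              n_up = sum(up), n_down = sum(down))
  ratios <- c(r_up_male_biased = counts[["up_male_biased"]] / n_mb,
              r_down_male_biased = counts[["down_male_biased"]] / n_mb,
              r_up_female_biased = counts[["up_female_biased"]] / n_fb,
              r_down_female_biased = counts[["down_female_biased"]] / n_fb)
  structure(list(condition = attr(perturb, "condition"),
                 time_point = attr(perturb, "time_point"),
                 sex = attr(perturb, "sex"),
                 ratios = ratios, counts = counts),
            class = "ResponsiveRatios")
}

#' @export
print.ResponsiveRatios <- function(x, ...) {
  cat("ResponsiveRatios for", x$sex, "under", x$condition,
      if (!is.na(x$time_point)) paste0("@", x$time_point), "\n")
  print(round(x$ratios, 4))
  invisible(x)
}

#' Inversion index of a responsive-ratio set
#'
#' A signed contrast in `[-2, 2]` that is positive exactly when the
#' affected sex up-regulates genes biased toward the opposite sex and
#' down-regulates genes biased toward its own sex (the inverted pattern).
#' For an affected-male contrast:
#' \deqn{(r_{up,female} + r_{down,male}) - (r_{up,male} + r_{down,female})}
#' and with the bias-class roles mirrored for an affected-female contrast.
#'
#' @param rr A [responsive_ratios()] result.
#' @return A single numeric index.
#' @export
inversion_index <- function(rr) {
  if (!inherits(rr, "ResponsiveRatios"))
    stop("`rr` must be a ResponsiveRatios", call. = FALSE)
  r <- rr$ratios
  if (rr$sex == "male")
    (r[["r_up_female_biased"]] + r[["r_down_male_biased"]]) -
      (r[["r_up_male_biased"]] + r[["r_down_female_biased"]])
  else
    (r[["r_up_male_biased"]] + r[["r_down_female_biased"]]) -
      (r[["r_up_female_biased"]] + r[["r_down_male_biased"]])
}

#' Label a condition by which sex shows the stronger inverted profile
#'
#' Computes the [inversion_index()] for the male and female contrasts of
#' one condition and labels it `male_inverted` if the male index exceeds
#' both the female index and the threshold `tau`; `female_inverted`
#' symmetrically; `none` otherwise. An exact tie above `tau` is labelled
#' `none` with `tie = TRUE`.
#'
#' @param rr_male,rr_female [responsive_ratios()] for the male and female
#'   contrasts of the same condition (and time point).
#' @param tau Decision threshold absorbing null noise (default 0.05).
#' @return An `"InversionProfile"`: list with `condition`, `time_point`,
#'   `index_male`, `index_female`, `label`, `tau`, `tie`.
#' @export
label_condition <- function(rr_male, rr_female, tau = 0.05) {
  if (!inherits(rr_male, "ResponsiveRatios") ||
      !inherits(rr_female, "ResponsiveRatios"))
    stop("inputs must be ResponsiveRatios", call. = FALSE)
  if (rr_male$sex != "male" || rr_female$sex != "female")
    stop("rr_male must be a male contrast and rr_female a female contrast",
         call. = FALSE)
  if (!identical(rr_male$condition, rr_female$condition) ||
      !identical(rr_male$time_point, rr_female$time_point))
    stop("condition/time-point mismatch between the two contrasts: '",
         rr_male$condition, "' vs '", rr_female$condition, "'",
         call. = FALSE)
  im <- inversion_index(rr_male)
  if_ <- inversion_index(rr_female)
  tie <- im == if_ && im > tau
  label <- if (im > if_ && im > tau) "male_inverted"
           else if (if_ > im && if_ > tau) "female_inverted"
           else "none"
  structure(list(condition = rr_male$condition,
                 time_point = rr_male$time_point,
                 index_male = im, index_female = if_,
                 label = label, tau = tau, tie = tie),
            class = "InversionProfile")
}

#' @export
print.InversionProfile <- function(x, ...) {
  cat(sprintf(
    "InversionProfile '%s'%s: index_male = %.3f, index_female = %.3f -> %s (tau = %g)\n",
    x$condition,
    if (!is.na(x$time_point)) paste0(" @", x$time_point) else "",
    x$index_male, x$index_female, x$label, x$tau))
  invisible(x)
}
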