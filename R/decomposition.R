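# Estimation of a root's indel spectrum from paired control/edited
# per-position base-signal matrices: the edited signal downstream of the cut
# is modelled as a non-negative mixture of indel-shifted copies of the
# control, fitted by non-negative least squares over sizes
# -max_indel..+max_indel, with per-size significance from an ordinary
# least-squares refit of the active set and an R^2 fit-quality measure.

validate_trace <- function(m, what = "trace") {
  if (!is.matrix(m) || ncol(m) != 4L)
    stop(what, " must be a matrix with 4 columns (A, C, G, T)")
  if (any(m < 0)) stop(what, " has negative signal fractions")
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop(what, " rows must each sum to 1")
  invisible(m)
}

#' Build indel-shifted templates from a control trace
#'
#' One template per size in `-max_indel..max_indel` (0 = wild type): rows up
#' to the cut equal the control; deletion templates shift the control rows
#' left by the deletion size; insertion templates shift right, with inserted
#' rows set to uniform 0.25 (inserted bases are unknown at fit time).
#'
#' @param control Control trace matrix (rows = positions, cols A/C/G/T).
#' @param cut_pos 1-based index of the base 5' of the cut.
#' @param max_indel Largest modelled indel size (bp).
#' @return Named list of matrices, names `"-30"`..`"30"`.
#' @export
build_templates <- function(control, cut_pos, max_indel = 30L) {
  validate_trace(control, "control")
  L <- nrow(control)
  if (cut_pos + max_indel >= L)
    stop("read too short: need cut_pos + max_indel < number of positions")
  sizes <- seq(-max_indel, max_indel)
  tpl <- lapply(sizes, function(s)
    allele_matrix(control, cut_pos, s, inserted_bases = NA))
  names(tpl) <- as.character(sizes)
  tpl
}

#' Decompose an edited trace into an indel spectrum
#'
#' Fits the edited signal over the decomposition window (rows
#' `cut_pos + max_indel + 1` to `L - max_indel`, where every template is
#' fully defined, flattened over the four base channels) as a non-negative
#' mixture of the indel-shifted templates. Coefficients are normalized to
#' percentages summing to 100. Each size's p-value comes from a two-sided
#' t-test of its coefficient in an ordinary least-squares refit restricted to
#' the active set; `r_squared` is `1 - SS_res/SS_tot` over the window.
#'
#' @param control,edited Paired trace matrices of equal dimensions.
#' @param cut_pos 1-based index of the base 5' of the cut.
#' @param thresholds A [default_thresholds()] (supplies `max_indel`).
#' @return List of class `"rootindel_decomposition"`: `spectrum` (an
#'   [indel_spectrum()] of all non-zero sizes with percentages and p-values),
#'   `wt_percentage`, `r_squared`, `window` (first/last fitted row),
#'   `percentages` and `p_values` (full per-size vectors, names -max..+max).
#' @export
decompose <- function(control, edited, cut_pos,
                      thresholds = default_thresholds()) {
  validate_trace(control, "control"); validate_trace(edited, "edited")
  if (!all(dim(control) == dim(edited)))
    stop("control and edited traces must have identical dimensions")
  max_indel <- thresholds$max_indel
  tpl <- build_templates(control, cut_pos, max_indel)
  L <- nrow(control)
  w0 <- cut_pos + max_indel + 1L
  w1 <- L - max_indel
  if (w1 - w0 + 1L < 20L)
    stop("decomposition window too short (", max(0L, w1 - w0 + 1L), " rows)")
  rows <- w0:w1
  y <- as.vector(edited[rows, ])
  X <- vapply(tpl, function(m) as.vector(m[rows, ]), numeric(length(y)))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("degenerate window: no signal variation")
  fit <- pracma::lsqnonneg(X, y)
  coef <- fit$x
  names(coef) <- colnames(X)
  total <- sum(coef)
  if (total <= 0) stop("degenerate fit: all coefficients zero")
  pct <- 100 * coef / total
  ss_res <- sum((y - X %*% coef)^2)
  r2 <- max(0, min(1, 1 - ss_res / ss_tot))
  p <- rep(1, length(coef))
  names(p) <- names(coef)
  active <- which(coef > 1e-10)
  if (length(active)) {
    Xa <- X[, active, drop = FALSE]
    ols <- stats::lm(y ~ 0 + Xa)
    df <- ols$df.residual
    sigma2 <- sum(ols$residuals^2) / max(df, 1L)
    if (sigma2 < 1e-24) {
      # numerically exact fit: active coefficients are unambiguous
      p[active] <- 0
    } else {
      sm <- summary(ols)$coefficients
      pa <- rep(1, length(active))
      pa[!is.na(stats::coef(ols))] <- sm[, "Pr(>|t|)"]
      p[active] <- pa
    }
  }
  sizes <- as.integer(names(coef))
  keep <- sizes != 0L & pct > 1e-9
  spectrum <- indel_spectrum(sizes[keep], pct[keep],
                             p_values = p[keep],
                             wt_percentage = pct[names(coef) == "0"])
  structure(list(spectrum = spectrum,
                 wt_percentage = unname(pct[names(coef) == "0"]),
                 r_squared = r2, window = c(start = w0, end = w1),
                 percentages = pct, p_values = p),
            class = "rootindel_decomposition")
}

#' Apply per-root and per-indel QC to a decomposition
#'
#' A root whose decomposition R^2 does not exceed `r2_cut` is rejected
#' outright; otherwise indels whose p-value is not below `p_cut` are dropped
#' and the surviving spectrum is returned.
#'
#' @param result A `"rootindel_decomposition"` from [decompose()].
#' @param thresholds A [default_thresholds()].
#' @return List of class `"rootindel_qc"`: `rejected` (logical), `reason`
#'   (`NA` or a message), `spectrum` (filtered spectrum, or `NULL` when the
#'   root is rejected), `r_squared`.
#' @export
filter_spectrum <- function(result, thresholds = default_thresholds()) {
  stopifnot(inherits(result, "rootindel_decomposition"))
  if (result$r_squared <= thresholds$r2_cut) {
    return(structure(list(rejected = TRUE,
                          reason = sprintf("R^2 = %.3f <= %.2f",
                                           result$r_squared,
                                           thresholds$r2_cut),
                          spectrum = NULL, r_squared = result$r_squared),
                     class = "rootindel_qc"))
  }
  sp <- result$spectrum
  keep <- !is.na(sp$p_value) & sp$p_value < thresholds$p_cut
  out <- indel_spectrum(sp$size[keep], sp$percentage[keep],
                        inserted_bases = sp$inserted_bases[keep],
                        p_values = sp$p_value[keep],
                        wt_percentage = attr(sp, "wt_percentage"))
  structure(list(rejected = FALSE, reason = NA_character_, spectrum = out,
                 r_squared = result$r_squared),
            class = "rootindel_qc")
}
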