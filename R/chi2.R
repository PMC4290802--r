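# Allelic-test machinery: genotype tables, HWE control derivation, and the
# 1-df chi-square statistic in both its tabular and x-parametrized forms.

#' Derive control genotype counts from a minor-allele frequency
#'
#' Expands a control-group minor-allele frequency into expected genotype
#' counts under Hardy-Weinberg equilibrium: `s0 = S(1-p)^2`,
#' `s1 = 2Sp(1-p)`, `s2 = Sp^2`. The three cells sum to `S` analytically,
#' so the derived row is exact, not rounded.
#'
#' @param maf Minor-allele frequency, a numeric vector with values in
#'   `[0, 1]`.
#' @param n_controls Number of control individuals `S` (positive scalar).
#' @param round_counts If `TRUE`, round each derived row to integers with
#'   largest-remainder rounding so the row still sums to `S` exactly.
#'   Default `FALSE`: the chi-square formula and the Hamming-score algorithm
#'   only require the case row to be integral, because privacy-relevant
#'   changes alter case records only.
#'
#' @return A tibble with one row per element of `maf` and columns
#'   `s0`, `s1`, `s2`.
#' @examples
#' hwe_control_genotypes(0.5, 100)
#' hwe_control_genotypes(c(0.1, 0.25), 174)
#' @export
hwe_control_genotypes <- function(maf, n_controls, round_counts = FALSE) {
  if (!is.numeric(maf) || any(!is.finite(maf)) || any(maf < 0 | maf > 1)) {
    stop("`maf` must be numeric in [0, 1].", call. = FALSE)
  }
  if (!is.numeric(n_controls) || length(n_controls) != 1L ||
      !is.finite(n_controls) || n_controls <= 0) {
    stop("`n_controls` must be a single positive number.", call. = FALSE)
  }
  s0 <- n_controls * (1 - maf)^2
  s1 <- 2 * n_controls * maf * (1 - maf)
  s2 <- n_controls * maf^2
  if (round_counts) {
    rounded <- t(vapply(
      seq_along(maf),
      function(i) largest_remainder_round(c(s0[i], s1[i], s2[i])),
      numeric(3)
    ))
    s0 <- rounded[, 1]; s1 <- rounded[, 2]; s2 <- rounded[, 3]
  }
  tibble::tibble(s0 = s0, s1 = s1, s2 = s2)
}

# Round non-negative reals to integers preserving their (integral) sum.
largest_remainder_round <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- x - fl
  short <- total - sum(fl)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[top] <- fl[top] + 1
  }
  fl
}

#' Collapse genotype counts to allelic counts
#'
#' Converts 2x3 genotype rows to the corresponding 2x2 allelic table cells:
#' each individual contributes two alleles, so the case minor-allele count is
#' `r1 + 2 r2`, the case major-allele count `2 r0 + r1`, and likewise for
#' controls. Row sums are `2R` and `2S`.
#'
#' @param panel A data frame with columns `r0, r1, r2, s0, s1, s2` (one SNP
#'   per row).
#' @return The input with columns `case_minor`, `case_major`,
#'   `control_minor`, `control_major` appended.
#' @examples
#' allelic_counts(tibble::tibble(r0 = 5, r1 = 3, r2 = 2,
#'                               s0 = 6, s1 = 2, s2 = 2))
#' @export
allelic_counts <- function(panel) {
  check_panel_counts(panel)
  dplyr::mutate(
    tibble::as_tibble(panel),
    case_minor    = .data$r1 + 2 * .data$r2,
    case_major    = 2 * .data$r0 + .data$r1,
    control_minor = .data$s1 + 2 * .data$s2,
    control_major = 2 * .data$s0 + .data$s1
  )
}

#' Allelic test statistic (1-df chi-square) for genotype tables
#'
#' Computes the allelic test statistic, equivalent to the Cochran-Armitage
#' trend test under the additive model:
#' \deqn{Y_A = \frac{2N\,[(2r_0+r_1)S - (2s_0+s_1)R]^2}
#'                  {R\,S\,(2n_0+n_1)(n_1+2n_2)}}
#' with \eqn{n_i = r_i + s_i}, \eqn{R = \sum r_i}, \eqn{S = \sum s_i},
#' \eqn{N = R + S}. It equals the Pearson chi-square on the 2x2 allelic
#' table.
#'
#' Monomorphic SNPs (a zero allelic column margin) force the numerator to
#' zero as well; by convention the statistic is returned as 0 with a warning
#' so that panel scoring never crashes. The Hamming-score functions refuse
#' such tables instead.
#'
#' @param r0,r1,r2 Case genotype counts by number of minor alleles
#'   (non-negative integers; vectors recycle as usual).
#' @param s0,s1,s2 Control genotype counts (non-negative reals; HWE-derived
#'   rows need not be integral).
#' @return Numeric vector of chi-square values (>= 0).
#' @examples
#' allelic_chi2(5, 3, 2, 10, 8, 2)
#' # proportional rows give 0
#' allelic_chi2(4, 4, 2, 8, 8, 4)
#' @export
allelic_chi2 <- function(r0, r1, r2, s0, s1, s2) {
  n <- vctrs::vec_size_common(r0, r1, r2, s0, s1, s2)
  args <- vctrs::vec_recycle_common(r0 = r0, r1 = r1, r2 = r2,
                                    s0 = s0, s1 = s1, s2 = s2, .size = n)
  r0 <- args$r0; r1 <- args$r1; r2 <- args$r2
  s0 <- args$s0; s1 <- args$s1; s2 <- args$s2
  if (any(c(r0, r1, r2, s0, s1, s2) < 0)) {
    stop("Genotype counts must be non-negative.", call. = FALSE)
  }
  R <- r0 + r1 + r2
  S <- s0 + s1 + s2
  if (any(R <= 0) || any(S <= 0)) {
    stop("Both case total R and control total S must be positive.",
         call. = FALSE)
  }
  N <- R + S
  major <- 2 * (r0 + s0) + (r1 + s1)   # 2n0 + n1
  minor <- (r1 + s1) + 2 * (r2 + s2)   # n1 + 2n2
  num <- 2 * N * ((2 * r0 + r1) * S - (2 * s0 + s1) * R)^2
  out <- numeric(length(R))
  zero_margin <- major == 0 | minor == 0
  if (any(zero_margin)) {
    warning("Monomorphic SNP(s) with a zero allelic margin: chi-square ",
            "set to 0 by convention.", call. = FALSE)
  }
  ok <- !zero_margin
  out[ok] <- num[ok] / (R[ok] * S[ok] * major[ok] * minor[ok])
  out
}

#' Allelic chi-square as a function of the case major-allele count
#'
#' Within the space of genotype tables sharing a control row and case total
#' `R`, every table with the same case major-allele count `x = 2 r0 + r1`
#' has the same allelic chi-square. This parametrization,
#' \deqn{Y_A(x) = \frac{2N (xS - n_{10}R)^2}{R S (x + n_{10})(2N - x - n_{10})},}
#' where `n10 = 2 s0 + s1` is the control major-allele count, is the engine
#' of the fast Hamming-score algorithm: the statistic is 0 at the vertex
#' `x = n10 R / S`, strictly decreasing in `x` left of it and strictly
#' increasing right of it.
#'
#' @param x Case major-allele count(s), in `[0, 2R]`.
#' @param n10 Control major-allele count `2 s0 + s1`, in `[0, 2S]`.
#' @param n_cases,n_controls Case and control totals `R`, `S`.
#' @return Numeric vector of chi-square values.
#' @examples
#' chi2_of_x(13, 14, 10, 20)           # == allelic_chi2(5,3,2, 10,8,2)
#' chi2_of_x(0:20, 120, 10, 100)       # a full profile over the triangle
#' @export
chi2_of_x <- function(x, n10, n_cases, n_controls) {
  R <- n_cases; S <- n_controls; N <- R + S
  if (any(x < 0) || any(x > 2 * R)) {
    stop("`x` must lie in [0, 2R].", call. = FALSE)
  }
  if (any(n10 < 0) || any(n10 > 2 * S)) {
    stop("`n10` must lie in [0, 2S].", call. = FALSE)
  }
  major <- x + n10
  minor <- 2 * N - x - n10
  if (any(major <= 0) || any(minor <= 0)) {
    stop("Zero allelic margin: chi2_of_x requires positive margins ",
         "(common-SNP assumption).", call. = FALSE)
  }
  2 * N * (x * S - n10 * R)^2 / (R * S * major * minor)
}

#' Chi-square significance threshold for a p-value
#'
#' Maps a threshold p-value `p*` to the critical value `c` of the 1-df
#' chi-square distribution: the upper-tail probability at `c` equals `p*`.
#' A table is called significant when its allelic statistic is `>= c`.
#'
#' @param p_star Threshold p-value, strictly between 0 and 1.
#' @return An object of class `chi2_threshold`: a list with elements
#'   `p_star` and `c`.
#' @examples
#' chi2_threshold(0.05)       # c ~ 3.8415
#' chi2_threshold(0.1 / 5000) # genome-wide style correction
#' @export
chi2_threshold <- function(p_star) {
  if (!is.numeric(p_star) || length(p_star) != 1L || !is.finite(p_star) ||
      p_star <= 0 || p_star >= 1) {
    stop("`p_star` must be a single number strictly between 0 and 1.",
         call. = FALSE)
  }
  structure(
    list(p_star = p_star,
         c = stats::qchisq(p_star, df = 1, lower.tail = FALSE)),
    class = "chi2_threshold"
  )
}

#' @export
print.chi2_threshold <- function(x, ...) {
  cat(sprintf("<chi2_threshold> p* = %g, c = %.6g (chi-square, 1 df)\n",
              x$p_star, x$c))
  invisible(x)
}

# Accept either a chi2_threshold or a bare p-value.
as_chi2_threshold <- function(threshold) {
  if (inherits(threshold, "chi2_threshold")) return(threshold)
  chi2_threshold(threshold)
}

#' Append the allelic chi-square score to a panel
#'
#' @param panel A SNP panel: a data frame with columns
#'   `snp_id, r0, r1, r2, s0, s1, s2`.
#' @return The panel with a `chi2` column appended.
#' @examples
#' panel <- simulate_panel(m = 10, n_cases = 50, n_controls = 50, seed = 1)
#' score_chi2(panel)
#' @export
score_chi2 <- function(panel) {
  check_panel(panel)
  dplyr::mutate(
    tibble::as_tibble(panel),
    chi2 = allelic_chi2(.data$r0, .data$r1, .data$r2,
                        .data$s0, .data$s1, .data$s2)
  )
}

# ---- panel validation ----------------------------------------------------

check_panel_counts <- function(panel, call. = FALSE) {
  needed <- c("r0", "r1", "r2", "s0", "s1", "s2")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    stop("Panel is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = call.)
  }
  for (col in needed) {
    v <- panel[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("Panel column `", col, "` must be finite, non-negative numeric.",
           call. = call.)
    }
  }
  case <- panel$r0 + panel$r1 + panel$r2
  bad <- which(abs(case - round(case)) > 1e-9 |
                 abs(panel$r0 - round(panel$r0)) > 1e-9 |
                 abs(panel$r1 - round(panel$r1)) > 1e-9 |
                 abs(panel$r2 - round(panel$r2)) > 1e-9)
  if (length(bad)) {
    stop("Case genotype counts must be integers (row ", bad[1], ").",
         call. = call.)
  }
  invisible(panel)
}

check_panel <- function(panel, call. = FALSE) {
  if (!is.data.frame(panel)) {
    stop("`panel` must be a data frame.", call. = call.)
  }
  if (!"snp_id" %in% names(panel)) {
    stop("Panel must have a `snp_id` column.", call. = call.)
  }
  if (anyDuplicated(panel$snp_id)) {
    stop("`snp_id` values must be unique.", call. = call.)
  }
  check_panel_counts(panel, call. = call.)
  invisible(panel)
}
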