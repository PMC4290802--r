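# Synthetic case-control panel generator and table-space enumeration.

#' Simulate a synthetic case-control SNP panel
#'
#' Generates a panel shaped like aggregate case-control GWAS data: `m` SNPs,
#' `n_cases` case individuals with 2x3 genotype counts, and a control row
#' derived deterministically from a per-SNP control minor-allele frequency
#' under Hardy-Weinberg equilibrium. For each SNP the control MAF `p` is
#' drawn uniformly from `maf_range`; null SNPs use case MAF `p' = p`, while
#' the first `n_assoc` SNPs get `p' = p + effect` (clipped to
#' `[0.01, 0.99]`). Case rows are drawn from a trinomial over the HWE
#' genotype probabilities at `p'` — the minimal case model consistent with
#' using HWE for the controls.
#'
#' Each SNP uses its own RNG substream derived from `seed` and the SNP
#' index, so enlarging `m` leaves earlier SNPs unchanged.
#'
#' @param m Number of SNPs.
#' @param n_cases,n_controls Case and control sample sizes `R`, `S`.
#' @param maf_range Lower/upper bounds of the uniform control-MAF
#'   distribution. Default `c(0.05, 0.5)`: safely above the 1% common-SNP
#'   floor so allelic margins stay positive even at small sample sizes.
#' @param n_assoc Number of truly associated SNPs (placed first in the
#'   panel; ids recorded in the `is_associated` column).
#' @param effect Case-control allele-frequency difference for associated
#'   SNPs.
#' @param seed Integer seed; the panel is a deterministic function of the
#'   arguments.
#' @return A tibble with columns `snp_id`, `r0, r1, r2`, `s0, s1, s2`,
#'   `control_maf`, `case_maf`, `is_associated`.
#' @examples
#' simulate_panel(m = 5, n_cases = 201, n_controls = 174, seed = 7)
#' @export
simulate_panel <- function(m, n_cases, n_controls,
                           maf_range = c(0.05, 0.5),
                           n_assoc = 0, effect = 0, seed = 1L) {
  if (m < 1 || n_cases < 1 || n_controls < 1) {
    stop("`m`, `n_cases`, `n_controls` must be positive.", call. = FALSE)
  }
  if (n_assoc < 0 || n_assoc > m) {
    stop("`n_assoc` must be between 0 and `m`.", call. = FALSE)
  }
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must satisfy 0.01 <= lower <= upper <= 0.5 ",
         "(common-SNP assumption).", call. = FALSE)
  }
  rows <- purrr::map(seq_len(m), function(i) {
    withr::with_seed(snp_substream_seed(seed, i), {
      p <- stats::runif(1, maf_range[1], maf_range[2])
      assoc <- i <= n_assoc
      p_case <- if (assoc) min(max(p + effect, 0.01), 0.99) else p
      probs <- c((1 - p_case)^2, 2 * p_case * (1 - p_case), p_case^2)
      r <- as.integer(stats::rmultinom(1, n_cases, probs))
      tibble::tibble(
        snp_id = sprintf("snp%05d", i),
        r0 = r[1], r1 = r[2], r2 = r[3],
        control_maf = p, case_maf = p_case, is_associated = assoc
      )
    })
  })
  panel <- dplyr::bind_rows(rows)
  ctrl <- hwe_control_genotypes(panel$control_maf, n_controls)
  out <- dplyr::bind_cols(
    panel[c("snp_id", "r0", "r1", "r2")],
    ctrl,
    panel[c("control_maf", "case_maf", "is_associated")]
  )
  check_panel(out)
  out
}

# Per-SNP substream seed: deterministic in (seed, i), kept inside the
# 32-bit integer range.
snp_substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Enumerate the full space of case rows for a fixed control row
#'
#' Yields every case row `(r0, r1, r2)` with non-negative integer cells
#' summing to `n_cases` — the `(R+1)(R+2)/2` lattice points of the triangle
#' — paired with the shared control row, in row-major order (`r0` ascending,
#' then `r1`).
#'
#' @inheritParams hamming_sensitivity
#' @return A panel tibble with one row per case configuration, `snp_id`
#'   values `"t<r0>_<r1>"`.
#' @examples
#' nrow(table_space(12, 40, 40, 20))  # 91
#' @export
table_space <- function(n_cases, s0, s1, s2) {
  R <- as.integer(n_cases)
  if (R < 1) stop("`n_cases` must be >= 1.", call. = FALSE)
  grid <- tidyr::expand_grid(r0 = 0:R, r1 = 0:R)
  grid <- dplyr::filter(grid, .data$r0 + .data$r1 <= R)
  dplyr::mutate(
    grid,
    snp_id = sprintf("t%d_%d", .data$r0, .data$r1),
    r2 = R - .data$r0 - .data$r1,
    s0 = s0, s1 = s1, s2 = s2,
    .before = 1
  )[, c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2")]
}
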