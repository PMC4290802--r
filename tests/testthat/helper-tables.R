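# Shared fixtures: independent oracles and random-table generators.

# Independent Pearson chi-square on a 2x2 table [a b; c d] of counts.
pearson_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Random valid genotype table with positive allelic margins.
random_table <- function() {
  R <- sample(5:60, 1)
  S <- sample(5:60, 1)
  repeat {
    r <- as.integer(stats::rmultinom(1, R, runif(3, 0.1, 1)))
    s <- as.integer(stats::rmultinom(1, S, runif(3, 0.1, 1)))
    minor <- (r[2] + s[2]) + 2 * (r[3] + s[3])
    major <- 2 * (r[1] + s[1]) + (r[2] + s[2])
    if (minor > 0 && major > 0) {
      return(list(r0 = r[1], r1 = r[2], r2 = r[3],
                  s0 = s[1], s1 = s[2], s2 = s[3], R = R, S = S))
    }
  }
}

# Small panel of hand-written tables sharing one control row (used by the
# exact differential-privacy ratio audit).
tiny_audit_panel <- function() {
  tibble::tibble(
    snp_id = c("a", "b", "c"),
    r0 = c(1L, 3L, 0L), r1 = c(2L, 2L, 1L), r2 = c(3L, 1L, 5L),
    s0 = 4, s1 = 4, s2 = 2
  )
}

# Panel engineered so the Hamming and chi-square rankings disagree at the
# top: `inv_highchi` has the larger chi-square, `inv_highham` the larger
# Hamming score (both strongly significant at p* = 0.01/40).
inversion_panel <- function() {
  ctrl05 <- hwe_control_genotypes(0.05, 100)
  ctrl20 <- hwe_control_genotypes(0.20, 100)
  filler <- simulate_panel(10, 100, 100, maf_range = c(0.2, 0.5), seed = 55)
  dplyr::bind_rows(
    tibble::tibble(snp_id = "inv_highchi", r0 = 0L, r1 = 0L, r2 = 100L,
                   s0 = ctrl20$s0, s1 = ctrl20$s1, s2 = ctrl20$s2),
    tibble::tibble(snp_id = "inv_highham", r0 = 14L, r1 = 0L, r2 = 86L,
                   s0 = ctrl05$s0, s1 = ctrl05$s1, s2 = ctrl05$s2),
    filler[c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2")]
  )
}
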