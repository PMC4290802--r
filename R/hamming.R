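# Exact shortest Hamming distance from a genotype table to the significance
# boundary, and the signed Hamming distance score built on it.
#
# Geometry: with the control row and R fixed, a case row (r0, r1, r2) is a
# lattice point in the triangle r0, r1 >= 0, r0 + r1 <= R. All tables with
# equal case major-allele count x = 2 r0 + r1 share one chi-square value
# (chi2_of_x), which is 0 at the vertex x = n10 R / S and unimodal around it,
# so the insignificant region {Y_A < c} is a contiguous band of x values
# straddling the vertex. One single-individual re-genotyping changes x by
# +/-1 or +/-2, which is what makes a fast directional walk exact.

# The six single-individual changes as (dr0, dr1) pairs; dr2 is implied.
SIX_MOVES <- matrix(
  c(+1L, 0L,   # r2 -> r0  (x + 2)
    +1L, -1L,  # r1 -> r0  (x + 1)
    0L, -1L,   # r1 -> r2  (x - 1)
    -1L, 0L,   # r0 -> r2  (x - 2)
    -1L, +1L,  # r0 -> r1  (x - 1)
    0L, +1L),  # r2 -> r1  (x + 1)
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("dr0", "dr1"))
)

#' Legal single-individual moves from a case row
#'
#' Re-genotyping one case individual changes the case row `(r0, r1, r2)` by
#' one of six moves: `(+1,0)`, `(+1,-1)`, `(0,-1)`, `(-1,0)`, `(-1,+1)`,
#' `(0,+1)` in `(dr0, dr1)`; the `r2` change is implied since the row sums
#' to `R`. A move is legal when the new row stays in the triangle
#' `r0, r1 >= 0`, `r0 + r1 <= R`. Interior rows have all 6 moves; corners
#' have 2.
#'
#' @param r0,r1 Case genotype counts (single non-negative integers).
#' @param n_cases Case total `R`.
#' @return A tibble with columns `dr0`, `dr1` (one legal move per row).
#' @examples
#' legal_moves(3, 4, 10)  # interior: 6 moves
#' legal_moves(10, 0, 10) # corner: 2 moves
#' @export
legal_moves <- function(r0, r1, n_cases) {
  R <- n_cases
  if (length(r0) != 1L || length(r1) != 1L || r0 < 0 || r1 < 0 ||
      r0 + r1 > R || r0 != round(r0) || r1 != round(r1)) {
    stop("(r0, r1) must be non-negative integers with r0 + r1 <= R.",
         call. = FALSE)
  }
  new_r0 <- r0 + SIX_MOVES[, "dr0"]
  new_r1 <- r1 + SIX_MOVES[, "dr1"]
  ok <- new_r0 >= 0 & new_r1 >= 0 & new_r0 + new_r1 <= R
  tibble::as_tibble(SIX_MOVES)[ok, ]
}

# Guard shared by the Hamming-score entry points. Returns n10.
check_hamming_table <- function(r0, r1, r2, s0, s1, s2) {
  R <- r0 + r1 + r2
  S <- s0 + s1 + s2
  if (R <= 0 || S <= 0) {
    stop("R and S must be positive.", call. = FALSE)
  }
  if (any(c(r0, r1, r2, s0, s1, s2) < 0) ||
      any(c(r0, r1, r2) != round(c(r0, r1, r2)))) {
    stop("Case counts must be non-negative integers; control counts ",
         "non-negative.", call. = FALSE)
  }
  n10 <- 2 * s0 + s1
  # A control row touching either allelic extreme puts a zero-margin table
  # inside the walk space; the score's geometry is undefined there.
  if (n10 <= 0 || n10 >= 2 * S) {
    stop("Unsupported table: monomorphic control row (zero allelic margin ",
         "reachable). Hamming scores require 0 < 2*s0 + s1 < 2S.",
         call. = FALSE)
  }
  n10
}

hamming_result <- function(distance, significant, branch) {
  list(
    distance = distance,
    score = if (significant) distance - 1L else -distance,
    significant = significant,
    branch = branch
  )
}

# First step index at which a directional walk becomes significant, else Inf.
# `deltas` is the per-step change in x, in walk order.
walk_until_significant <- function(x, deltas, n10, R, S, c) {
  if (!length(deltas)) return(Inf)
  xs <- x + cumsum(deltas)
  hit <- which(chi2_of_x(xs, n10, R, S) >= c)
  if (length(hit)) hit[1] else Inf
}

#' Exact shortest Hamming distance score of a genotype table
#'
#' Computes the smallest number of single-individual changes to the case row
#' that flips the table's significance status under the allelic test at
#' threshold `c`, and the signed score built on it: `h = -(distance)` for an
#' insignificant table (`Y_A < c`), `h = distance - 1` for a significant one
#' (`Y_A >= c`). The score has sensitivity 1, which is what lets the
#' exponential mechanism use it with exponent scale `eps / (2K)`.
#'
#' For an insignificant table the algorithm runs two directional walks on
#' the case major-allele count `x`: downward (decrement `r0` while possible,
#' each step `-2` in `x`, then decrement `r1`, each `-1`) and upward
#' (increment `r0` from `r2`, each `+2`, then trade `r1` for `r0`, each
#' `+1`), counting steps until the statistic reaches `c`; the distance is
#' the smaller count. If no significant table exists in the space, the
#' distance is `1 + min(d1, d2)` where `d1 = r0 + r1`, `d2 = R - r0` are the
#' step counts to the triangle's extreme corners. For a significant table
#' the single feasible walk moves `x` toward the vertex `n10 R / S` and
#' lands exactly on the nearest insignificant `x`; the walk on the far side
#' of the vertex can never cross into insignificance and is discarded.
#'
#' @param r0,r1,r2 Case genotype counts (non-negative integers).
#' @param s0,s1,s2 Control genotype counts (non-negative reals with
#'   `0 < 2 s0 + s1 < 2S`; monomorphic control rows are refused).
#' @param threshold A [chi2_threshold()] object, or a bare p-value in (0,1).
#' @return A list with elements `distance` (positive integer), `score`
#'   (integer `h`), `significant` (logical), and `branch` (which walk
#'   attained the minimum: `"down"`, `"up"`, `"corner_down"`,
#'   `"corner_up"`).
#' @seealso [hamming_distance_bfs()] for the brute-force oracle,
#'   [hamming_sensitivity()] for the exhaustive sensitivity audit.
#' @examples
#' hamming_distance(5, 3, 2, 40, 40, 20, threshold = 0.05)
#' @export
hamming_distance <- function(r0, r1, r2, s0, s1, s2, threshold) {
  thr <- as_chi2_threshold(threshold)
  n10 <- check_hamming_table(r0, r1, r2, s0, s1, s2)
  R <- r0 + r1 + r2
  S <- s0 + s1 + s2
  c <- thr$c
  x <- 2 * r0 + r1
  significant <- chi2_of_x(x, n10, R, S) >= c
  xstar <- n10 * R / S

  if (!significant) {
    h1 <- walk_until_significant(x, rep(c(-2L, -1L), c(r0, r1)),
                                 n10, R, S, c)
    h2 <- walk_until_significant(x, rep(c(2L, 1L), c(R - r0 - r1, r1)),
                                 n10, R, S, c)
    if (is.finite(h1) || is.finite(h2)) {
      if (h1 <= h2) {
        return(hamming_result(as.integer(h1), FALSE, "down"))
      }
      return(hamming_result(as.integer(h2), FALSE, "up"))
    }
    # Whole space insignificant: one step past the nearer extreme corner.
    d1 <- r0 + r1       # steps to (0, 0)
    d2 <- R - r0        # steps to (R, 0)
    if (d1 <= d2) {
      return(hamming_result(1L + as.integer(d1), FALSE, "corner_down"))
    }
    return(hamming_result(1L + as.integer(d2), FALSE, "corner_up"))
  }

  # Significant table: walk x toward the vertex; land exactly on the first
  # insignificant x (a -2/+2 step may not overshoot the band).
  if (x > xstar) {
    targets <- seq(x - 1L, 0L)
    hit <- which(chi2_of_x(targets, n10, R, S) < c)
    if (!length(hit)) {
      stop("No insignificant table exists in this table space ",
           "(threshold c is below the minimum chi-square on the grid).",
           call. = FALSE)
    }
    delta <- hit[1]                       # x - x_hi
    doubles <- r0
    branch <- "down"
  } else {
    # x < xstar (a significant table cannot sit on the vertex: Y_A = 0 < c)
    targets <- seq(x + 1L, 2L * R)
    hit <- which(chi2_of_x(targets, n10, R, S) < c)
    if (!length(hit)) {
      stop("No insignificant table exists in this table space ",
           "(threshold c is below the minimum chi-square on the grid).",
           call. = FALSE)
    }
    delta <- hit[1]                       # x_lo - x
    doubles <- R - r0 - r1
    branch <- "up"
  }
  d <- max(ceiling(delta / 2), delta - doubles)
  hamming_result(as.integer(d), TRUE, branch)
}

#' Brute-force BFS oracle for the shortest Hamming distance
#'
#' Breadth-first search over the full triangle of case rows, using
#' [legal_moves()] as the adjacency relation, until the first row whose
#' significance status differs from the start's. Exponentially slower than
#' [hamming_distance()] in spirit (it touches the whole space), but defined
#' directly from the distance's definition, so it serves as the independent
#' oracle in tests. Intended for small `R`.
#'
#' @inheritParams hamming_distance
#' @return Same structure as [hamming_distance()] except `branch` is
#'   `"bfs"` (or `"bfs_corner"` for the unreachable-significance fallback).
#' @export
hamming_distance_bfs <- function(r0, r1, r2, s0, s1, s2, threshold) {
  thr <- as_chi2_threshold(threshold)
  n10 <- check_hamming_table(r0, r1, r2, s0, s1, s2)
  R <- as.integer(r0 + r1 + r2)
  S <- s0 + s1 + s2
  c <- thr$c

  sig_of <- function(a0, a1) chi2_of_x(2 * a0 + a1, n10, R, S) >= c
  start_sig <- sig_of(r0, r1)

  bfs_depth <- function(goal) {
    # goal(a0, a1) -> logical; min depth from (r0, r1) to a goal state, or Inf
    seen <- matrix(FALSE, nrow = R + 1, ncol = R + 1)
    seen[r0 + 1, r1 + 1] <- TRUE
    frontier <- matrix(c(r0, r1), ncol = 2)
    depth <- 0L
    repeat {
      if (nrow(frontier) == 0) return(Inf)
      if (any(goal(frontier[, 1], frontier[, 2]))) return(depth)
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        mv <- legal_moves(frontier[i, 1], frontier[i, 2], R)
        b0 <- frontier[i, 1] + mv$dr0
        b1 <- frontier[i, 2] + mv$dr1
        new <- !seen[cbind(b0 + 1, b1 + 1)]
        if (any(new)) {
          seen[cbind(b0[new] + 1, b1[new] + 1)] <- TRUE
          nxt <- rbind(nxt, cbind(b0[new], b1[new]))
        }
      }
      frontier <- if (is.null(nxt)) matrix(integer(0), ncol = 2) else nxt
      depth <- depth + 1L
    }
  }

  d_flip <- bfs_depth(function(a0, a1) sig_of(a0, a1) != start_sig)
  if (is.finite(d_flip)) {
    return(hamming_result(as.integer(d_flip), start_sig, "bfs"))
  }
  if (start_sig) {
    stop("No insignificant table exists in this table space ",
         "(threshold c is below the minimum chi-square on the grid).",
         call. = FALSE)
  }
  d1 <- bfs_depth(function(a0, a1) a0 == 0 & a1 == 0)
  d2 <- bfs_depth(function(a0, a1) a0 == R & a1 == 0)
  hamming_result(1L + as.integer(min(d1, d2)), FALSE, "bfs_corner")
}

#' Append Hamming distance scores to a panel
#'
#' Vectorizes [hamming_distance()] over a SNP panel. Unsupported tables
#' (monomorphic control rows, or spaces with no insignificant table) raise
#' an error naming the offending `snp_id`.
#'
#' @inheritParams score_chi2
#' @param threshold A [chi2_threshold()] or bare p-value.
#' @return The panel with columns `hamming` (the score `h`),
#'   `hamming_distance`, and `significant` appended.
#' @examples
#' panel <- simulate_panel(m = 20, n_cases = 30, n_controls = 30, seed = 2)
#' score_hamming(panel, threshold = 0.05)
#' @export
score_hamming <- function(panel, threshold) {
  check_panel(panel)
  thr <- as_chi2_threshold(threshold)
  res <- purrr::pmap(
    panel[c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2")],
    function(snp_id, r0, r1, r2, s0, s1, s2) {
      tryCatch(
        hamming_distance(r0, r1, r2, s0, s1, s2, thr),
        error = function(e) {
          stop("SNP `", snp_id, "`: ", conditionMessage(e), call. = FALSE)
        }
      )
    }
  )
  dplyr::mutate(
    tibble::as_tibble(panel),
    hamming = vapply(res, `[[`, integer(1), "score"),
    hamming_distance = vapply(res, `[[`, integer(1), "distance"),
    significant = vapply(res, `[[`, logical(1), "significant")
  )
}

#' Exhaustive empirical sensitivity of the Hamming distance score
#'
#' Enumerates every case row in the table space defined by `n_cases` and a
#' fixed control row, scores each with [hamming_distance()], and returns the
#' maximum absolute score difference over all pairs of rows connected by
#' one legal move. By construction of the shortest distance this maximum is
#' 1 whenever the significance boundary is crossable; the function is the
#' audit that verifies it.
#'
#' @param n_cases Case total `R` (kept small; the space has
#'   `(R+1)(R+2)/2` rows).
#' @param s0,s1,s2 Fixed control row.
#' @inheritParams hamming_distance
#' @return A single non-negative integer.
#' @examples
#' hamming_sensitivity(10, 40, 40, 20, threshold = 0.05)  # 1
#' @export
hamming_sensitivity <- function(n_cases, s0, s1, s2, threshold) {
  thr <- as_chi2_threshold(threshold)
  space <- table_space(n_cases, s0, s1, s2)
  scored <- score_hamming(space, thr)
  h <- scored$hamming
  key <- scored$r0 * (n_cases + 1L) + scored$r1
  idx <- integer(max(key) + 1L)
  idx[key + 1L] <- seq_along(key)
  worst <- 0L
  for (i in seq_len(nrow(scored))) {
    mv <- legal_moves(scored$r0[i], scored$r1[i], n_cases)
    j <- idx[(scored$r0[i] + mv$dr0) * (n_cases + 1L) +
               (scored$r1[i] + mv$dr1) + 1L]
    worst <- max(worst, abs(h[j] - h[i]))
  }
  as.integer(worst)
}

#' Exhaustive empirical sensitivity of the allelic chi-square score
#'
#' Maximum absolute change in the allelic chi-square over all one-move
#' neighbour pairs in an enumerated table space. The chi-square score has
#' no printed closed-form sensitivity here, so the chi-square-score
#' mechanisms require an explicit sensitivity; this auditor lets users
#' justify a value empirically on spaces shaped like their data.
#'
#' @inheritParams hamming_sensitivity
#' @return A single non-negative number.
#' @examples
#' chi2_sensitivity(10, 40, 40, 20)
#' @export
chi2_sensitivity <- function(n_cases, s0, s1, s2) {
  R <- as.integer(n_cases)
  S <- s0 + s1 + s2
  n10 <- 2 * s0 + s1
  x <- 0:(2L * R)
  y <- chi2_of_x(x, n10, R, S)
  # one move changes x by at most 2, so neighbour differences are bounded
  # by max over |Y(x) - Y(x +/- k)|, k in {1, 2}
  max(abs(diff(y, lag = 1)), abs(diff(y, lag = 2)))
}
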