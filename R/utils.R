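#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' generator functions are reproducible without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# lognormal draws parameterized by arithmetic mean and CV; cv = 0 gives the
# constant mean
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(mean >= 0, cv >= 0)
  # a zero mean degenerates to exact zeros (e.g. no activity cost at all)
  if (mean == 0 || cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# standard error of the mean
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# compact numeric label: 2.5 -> "2.5", 14 -> "14"
num_label <- function(x) {
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 3))
}

# paired two-sided p-value robust to zero-variance differences
paired_p <- function(x, y, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2) return(NA_real_)
  if (stats::sd(d) == 0) {
    return(if (all(d == 0)) 1 else 0)
  }
  if (test == "t") {
    stats::t.test(d)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(d)$p.value)
  }
}
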