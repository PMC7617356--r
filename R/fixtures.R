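# Tiny deterministic datasets used by the test-suite and examples.

#' Deterministic benchmark fixtures
#'
#' \describe{
#'   \item{separable}{n = 200, 10% prevalence; `x1` separates the classes
#'     with margin 0.5 (positives at `x1 >= 0.5`, negatives at
#'     `x1 <= -0.5`), plus four standard-normal noise features.}
#'   \item{null}{n = 200, 10% prevalence, five noise features and an
#'     outcome independent of all of them.}
#'   \item{planted_logistic}{Balanced logistic outcome driven by two
#'     dominant features with coefficients +3 and -3 (signal features have
#'     sd 2 so the Bayes F1 is about 0.94), plus three standard-normal
#'     noise features.}
#' }
#'
#' @param name Fixture name.
#' @param n Number of rows (default 200; `planted_logistic` defaults to
#'   2000).
#' @param seed Integer seed.
#' @return list: `X` (matrix, columns `x1`..`x5`), `y` (0/1 vector).
#' @export
make_fixture <- function(name, n = NULL, seed = 1) {
  switch(name,
    separable = {
      n <- if (is.null(n)) 200L else n
      n_pos <- max(1L, round(0.1 * n))
      with_seed(substream_seed(seed, "separable"), {
        x1 <- c(stats::runif(n_pos, 0.5, 2), stats::runif(n - n_pos, -2, -0.5))
        noise <- matrix(stats::rnorm(n * 4), nrow = n)
        X <- cbind(x1, noise)
        colnames(X) <- paste0("x", 1:5)
        ord <- shuffle_(seq_len(n))
        list(X = X[ord, , drop = FALSE],
             y = c(rep(1L, n_pos), rep(0L, n - n_pos))[ord])
      })
    },
    null = {
      n <- if (is.null(n)) 200L else n
      with_seed(substream_seed(seed, "null"), {
        X <- matrix(stats::rnorm(n * 5), nrow = n,
                    dimnames = list(NULL, paste0("x", 1:5)))
        list(X = X, y = stats::rbinom(n, 1L, 0.1))
      })
    },
    planted_logistic = {
      n <- if (is.null(n)) 2000L else n
      with_seed(substream_seed(seed, "planted"), {
        X <- cbind(matrix(stats::rnorm(n * 2, 0, 2), nrow = n),
                   matrix(stats::rnorm(n * 3), nrow = n))
        colnames(X) <- paste0("x", 1:5)
        p <- stats::plogis(3 * X[, "x1"] - 3 * X[, "x2"])
        list(X = X, y = stats::rbinom(n, 1L, p))
      })
    },
    stop("unknown fixture name: ", name)
  )
}
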