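#' Heritability of a two-locus penetrance function
#'
#' Under Hardy-Weinberg equilibrium and linkage equilibrium at both loci,
#' the population prevalence of high-risk status is
#' `K = sum_g P(g) f(g)` and the (broad-sense, binary-trait) heritability is
#' the variance of the penetrance over the binomial variance of the status,
#' \deqn{h^2 = \frac{\sum_g P(g) (f(g) - K)^2}{K (1 - K)},}
#' with `P(g)` the product of the two HWE genotype probabilities.
#'
#' @param f 3x3 penetrance matrix; rows index the minor-allele count (0/1/2)
#'   at the first locus, columns at the second.
#' @param maf Minor allele frequency, shared by both loci.
#' @return Heritability, with attribute `prevalence` (K).
#' @examples
#' f <- matrix(0.1 * (outer(0:2, 0:2, `+`) %% 2), 3, 3)
#' heritability(f, maf = 0.5)
#' @export
heritability <- function(f, maf) {
  stopifnot(is.matrix(f), all(dim(f) == c(3, 3)))
  if (any(f < 0 | f > 1)) stop("penetrances must lie in [0, 1]", call. = FALSE)
  w <- hwe_probs(maf)
  pg <- outer(w, w)
  k <- sum(pg * f)
  if (k <= 0 || k >= 1) {
    stop("prevalence K = ", k, " leaves heritability undefined", call. = FALSE)
  }
  structure(sum(pg * (f - k)^2) / (k * (1 - k)), prevalence = k)
}

hwe_probs <- function(maf) {
  stopifnot(maf > 0, maf < 1)
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Generate a pure-epistasis penetrance model
#'
#' Draws a 3x3 penetrance function with exactly the requested heritability
#' and *no* marginal effects at either locus. The construction samples the
#' null space of the marginal-effect constraints directly: any matrix
#' `E = U C U'` — with `U` a basis of the HWE-weight-orthogonal complement
#' and `C` a random 2x2 coefficient matrix — has HWE-weighted row and column
#' sums of zero, so `f = K + c E` keeps both marginal penetrances constant
#' at the prevalence `K` while `c` is solved in closed form to hit the
#' heritability target. Random restarts only reject draws whose penetrances
#' leave \[0, 1\]; accepted models satisfy the tolerance to floating-point
#' accuracy rather than approximately.
#'
#' @param maf Minor allele frequency (both loci).
#' @param h2 Target heritability.
#' @param seed Seed for the random restarts.
#' @param tol Accepted deviation of the realised heritability from `h2`.
#' @param marginal_eps Accepted range of each locus's marginal penetrance.
#' @param max_tries Restart cap; exhausting it is an error reporting the best
#'   deviation achieved.
#' @param prevalence_range Interval from which the prevalence K is drawn
#'   uniformly at each restart.
#' @return An object of class `penetrance_model`: list with `f`, `maf`,
#'   `prevalence`, `h2` (realised), `h2_target`.
#' @export
penetrance_model <- function(maf, h2, seed = 1L, tol = 0.01,
                             marginal_eps = 0.01, max_tries = 1000L,
                             prevalence_range = c(0.01, 0.5)) {
  stopifnot(h2 > 0, h2 < 1, max_tries >= 1)
  w <- hwe_probs(maf)
  u <- cbind(c(w[2], -w[1], 0), c(0, w[3], -w[2]))
  best_dev <- Inf
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      cmat <- matrix(stats::rnorm(4), 2, 2)
      e <- u %*% cmat %*% t(u)
      var_e <- sum(outer(w, w) * e^2)
      if (var_e < 1e-12) next
      k <- stats::runif(1, prevalence_range[1], prevalence_range[2])
      scale <- sqrt(h2 * k * (1 - k) / var_e)
      f <- k + scale * e
      if (any(f < 0 | f > 1)) {
        # track how close an in-range rescaling could get
        room <- min((1 - k) / max(scale * e), -k / min(scale * e))
        best_dev <- min(best_dev, h2 * (1 - max(0, room)^2))
        next
      }
      h2_real <- heritability(f, maf)
      marg <- marginal_ranges(f, w)
      if (abs(h2_real - h2) <= tol && max(marg) <= marginal_eps) {
        return(structure(
          list(f = f, maf = maf, prevalence = attr(h2_real, "prevalence"),
               h2 = as.numeric(h2_real), h2_target = h2),
          class = "penetrance_model"
        ))
      }
      best_dev <- min(best_dev, abs(h2_real - h2))
    }
  })
  stop("no penetrance model within tol = ", tol, " after ", max_tries,
       " tries (best heritability deviation ", signif(best_dev, 3), ")",
       call. = FALSE)
}

# Range of each locus's marginal penetrance (0 for pure epistasis).
marginal_ranges <- function(f, w) {
  m1 <- as.vector(f %*% w)      # marginal penetrance by locus-1 genotype
  m2 <- as.vector(t(f) %*% w)
  c(diff(range(m1)), diff(range(m2)))
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("<penetrance_model> maf = %.2f, h2 = %.3f, prevalence K = %.3f\n",
              x$maf, x$h2, x$prevalence))
  print(round(x$f, 4))
  invisible(x)
}

#' Tidy a penetrance model
#'
#' @param x A `penetrance_model`.
#' @param ... Unused.
#' @return One row per genotype cell: allele counts `g1`, `g2`, HWE cell
#'   probability `prob` and penetrance `f`.
#' @export
tidy.penetrance_model <- function(x, ...) {
  w <- hwe_probs(x$maf)
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  tibble::tibble(
    g1 = grid$g1, g2 = grid$g2,
    prob = w[grid$g1 + 1] * w[grid$g2 + 1],
    f = x$f[cbind(grid$g1 + 1, grid$g2 + 1)]
  )
}

#' Batch of penetrance models over a MAF-by-heritability grid
#'
#' Generates `n_models` independent penetrance realisations for every
#' combination of the supplied minor allele frequencies and heritabilities —
#' the default grid (2 MAFs x 4 heritabilities x 5 models) yields the 40
#' epistatic models of the simulation benchmark.
#'
#' @param mafs,h2s Grid values.
#' @param n_models Models per combination.
#' @param seed Master seed; each model gets an independent child seed.
#' @param ... Passed on to [penetrance_model()].
#' @return Tibble with columns `maf`, `h2`, `replicate` and a `model`
#'   list-column.
#' @export
penetrance_grid <- function(mafs = c(0.2, 0.4), h2s = c(0.1, 0.2, 0.3, 0.4),
                            n_models = 5, seed = 1L, ...) {
  grid <- tidyr::expand_grid(maf = mafs, h2 = h2s,
                             replicate = seq_len(n_models))
  seeds <- child_seeds(seed, nrow(grid))
  grid$model <- purrr::pmap(
    list(grid$maf, grid$h2, seeds),
    function(maf, h2, s, ...) penetrance_model(maf, h2, seed = s, ...),
    ...
  )
  grid
}
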