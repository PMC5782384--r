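# Multipoint genotype probabilities for an F2-coded intercross via a
# three-state hidden Markov model (states AA, AB, BB), evaluated on a grid
# of markers plus pseudomarkers. The AIL is analysed with F2 transition
# probabilities on the observed (already expanded) map, the same
# approximation applied when an advanced intercross is coded as an F2
# intercross; recombination fractions come from the Haldane map function.

haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

# F2 two-locus transition matrix for recombination fraction r (rows: state
# at the left locus AA/AB/BB, columns: state at the right locus).
f2_transition <- function(r) {
  matrix(c((1 - r)^2,     2 * r * (1 - r), r^2,
           r * (1 - r),   (1 - r)^2 + r^2, r * (1 - r),
           r^2,           2 * r * (1 - r), (1 - r)^2),
         nrow = 3, byrow = TRUE)
}

# Emission probabilities P(observed code | true state) for genotyping-error
# rate eps. Rows: observed code 1..5; columns: true state AA/AB/BB. A fully
# informative observation is correct with probability 1 - eps, with errors
# spread uniformly over the other codes; partially informative codes sum
# the two compatible full-code emissions.
emission_table <- function(eps) {
  full <- matrix(eps / 2, 3, 3)
  diag(full) <- 1 - eps
  rbind(full,
        notBB = full[1, ] + full[2, ],   # observed AA-or-AB
        notAA = full[2, ] + full[3, ])
}

# Pseudomarker grid for one chromosome: markers plus equally spaced points
# every `step` cM, duplicates (within 1e-6) removed in favour of markers.
chr_grid <- function(pos_cm, step) {
  lo <- min(pos_cm); hi <- max(pos_cm)
  extra <- if (hi > lo) seq(lo, hi, by = step) else numeric(0)
  keep <- vapply(extra, function(p) all(abs(p - pos_cm) > 1e-6), TRUE)
  grid <- sort(c(pos_cm, extra[keep]))
  attr(grid, "marker_index") <- match(round(pos_cm, 8), round(grid, 8))
  grid
}

#' Multipoint genotype probabilities
#'
#' Forward-backward over a 3-state chain (AA/AB/BB) per chromosome, on a grid
#' of markers plus pseudomarkers at a fixed cM step. Transition probabilities
#' follow the F2 intercross model with Haldane recombination fractions;
#' emissions allow a genotyping-error rate and partially informative codes
#' (not-AA / not-BB) that emit over their compatible state set. Missing
#' observations are uninformative.
#'
#' @param cross An `ail_cross`.
#' @param step Pseudomarker spacing in cM (> 0).
#' @param error_prob Genotyping error rate, in \[0, 0.5).
#' @return An object of class `ail_genoprob`: list with `prob` (per
#'   chromosome, an array individuals x positions x 3), `grid` (data frame
#'   `chr`, `pos_cm`, `pos_mb`, `marker`), `step`, `error_prob`.
#' @export
calc_genoprob <- function(cross, step = 1, error_prob = 0.001) {
  if (step <= 0) stop("step must be > 0")
  if (error_prob < 0 || error_prob >= 0.5) stop("error_prob must be in [0, 0.5)")
  emit <- emission_table(error_prob)
  prior <- c(0.25, 0.5, 0.25)
  n <- nrow(cross$geno)
  chrs <- unique(cross$map$chr)
  has_mb <- any(!is.na(cross$map$pos_mb))
  prob <- list()
  grid_all <- NULL
  for (ch in chrs) {
    idx <- which(cross$map$chr == ch)
    if (!length(idx)) stop("empty chromosome ", ch)
    pos <- cross$map$pos_cm[idx]
    grid <- chr_grid(pos, step)
    midx <- attr(grid, "marker_index")
    K <- length(grid)
    # emissions at grid positions: uninformative except at markers
    E <- vector("list", K)
    for (j in seq_along(idx)) {
      obs <- cross$geno[, idx[j]]
      Ej <- matrix(1, n, 3)
      typed <- !is.na(obs)
      if (any(typed)) Ej[typed, ] <- emit[obs[typed], , drop = FALSE]
      k <- midx[j]
      E[[k]] <- if (is.null(E[[k]])) Ej else E[[k]] * Ej
    }
    Tm <- lapply(seq_len(max(K - 1, 0)), function(k)
      f2_transition(haldane_r(grid[k + 1] - grid[k])))
    # forward
    alpha <- vector("list", K)
    a <- matrix(prior, n, 3, byrow = TRUE)
    if (!is.null(E[[1]])) a <- a * E[[1]]
    a <- a / rowSums(a)
    alpha[[1]] <- a
    if (K > 1) for (k in 2:K) {
      a <- alpha[[k - 1]] %*% Tm[[k - 1]]
      if (!is.null(E[[k]])) a <- a * E[[k]]
      a <- a / rowSums(a)
      alpha[[k]] <- a
    }
    # backward
    post <- array(0, dim = c(n, K, 3))
    b <- matrix(1, n, 3)
    post[, K, ] <- alpha[[K]]
    if (K > 1) for (k in (K - 1):1) {
      be <- b
      if (!is.null(E[[k + 1]])) be <- be * E[[k + 1]]
      b <- be %*% t(Tm[[k]])
      b <- b / rowSums(b)
      p <- alpha[[k]] * b
      post[, k, ] <- p / rowSums(p)
    }
    dimnames(post) <- list(rownames(cross$geno), NULL, c("AA", "AB", "BB"))
    prob[[ch]] <- post
    marker <- rep(NA_character_, K)
    marker[midx] <- cross$map$marker[idx]
    pos_mb <- if (has_mb)
      tryCatch(cm_to_mb(cross$map, ch, grid), error = function(e) rep(NA_real_, K))
    else rep(NA_real_, K)
    grid_all <- rbind(grid_all, data.frame(
      chr = ch, pos_cm = as.numeric(grid), pos_mb = pos_mb, marker = marker,
      stringsAsFactors = FALSE))
  }
  structure(list(prob = prob, grid = grid_all, step = step,
                 error_prob = error_prob),
            class = "ail_genoprob")
}

#' @export
print.ail_genoprob <- function(x, ...) {
  cat("ail_genoprob:", nrow(x$grid), "grid positions on",
      length(x$prob), "chromosomes; step", x$step, "cM, error_prob",
      x$error_prob, "\n")
  invisible(x)
}

#' Haley-Knott regression scores from genotype probabilities
#'
#' The additive score is `x_a = P(BB) - P(AA)` (in \[-1, 1\], positive for
#' the domestic-founder allele) and the dominance score `x_d = P(AB)`
#' (in \[0, 1\]).
#'
#' @param gp An `ail_genoprob` object.
#' @return List with matrices `xa`, `xd` (individuals x grid positions) and
#'   the `grid` data frame.
#' @export
genotype_scores <- function(gp) {
  take <- function(p, f) matrix(f(p), nrow = dim(p)[1])
  xa <- do.call(cbind, lapply(gp$prob, function(p) take(p, function(q) q[, , 3] - q[, , 1])))
  xd <- do.call(cbind, lapply(gp$prob, function(p) take(p, function(q) q[, , 2])))
  list(xa = xa, xd = xd, grid = gp$grid)
}
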