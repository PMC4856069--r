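#' Genotype probabilities along the map
#'
#' Hidden-Markov forward-backward computation of P(AB) for every individual at
#' every marker and pseudomarker position of a backcross. States are
#' \{AA, AB\} with prior 1/2 each; transitions between adjacent grid positions
#' use the Haldane recombination fraction of the intervening distance (no
#' interference); an observed genotype is emitted correctly with probability
#' 1 - \code{error_prob}, and a missing genotype emits uniformly.
#'
#' @param cross a \code{bc_cross}.
#' @param step pseudomarker spacing in cM (0 = markers only). Pseudomarkers
#'   are equally spaced fill-ins between markers; all markers are kept on the
#'   grid.
#' @param error_prob genotyping-error prior in [0, 0.5).
#' @return object of class \code{"genoprob"}: list per chromosome with
#'   \code{pos} (grid positions), \code{marker} (logical), \code{prob}
#'   (n x length(pos) matrix of P(AB)); attributes \code{step},
#'   \code{error_prob}.
#' @export
calc_genoprob <- function(cross, step = 1, error_prob = 0.001) {
  if (step < 0) stop("step must be >= 0")
  if (error_prob < 0 || error_prob >= 0.5) stop("error_prob must be in [0, 0.5)")
  out <- list()
  for (ch in names(cross$map)) {
    mp <- cross$map[[ch]]
    if (length(mp) == 0L) stop("empty chromosome ", ch)
    grid <- grid_positions(mp, step)
    g <- cross$geno[[ch]]
    n <- nrow(g)
    npos <- length(grid$pos)
    ## emission matrix at grid positions: rows individuals, e0/e1 = P(obs|AA/AB)
    e0 <- matrix(1, n, npos); e1 <- matrix(1, n, npos)
    obs_col <- grid$marker_index
    for (j in seq_along(mp)) {
      col <- obs_col[j]
      gj <- g[, j]
      typed <- !is.na(gj)
      e0[typed, col] <- ifelse(gj[typed] == 0L, 1 - error_prob, error_prob)
      e1[typed, col] <- ifelse(gj[typed] == 1L, 1 - error_prob, error_prob)
    }
    r <- haldane(diff(grid$pos))
    ## forward
    f0 <- matrix(0, n, npos); f1 <- matrix(0, n, npos)
    f0[, 1L] <- 0.5 * e0[, 1L]; f1[, 1L] <- 0.5 * e1[, 1L]
    sc <- f0[, 1L] + f1[, 1L]
    f0[, 1L] <- f0[, 1L] / sc; f1[, 1L] <- f1[, 1L] / sc
    for (j in seq_len(npos - 1L)) {
      rj <- r[j]
      a0 <- f0[, j] * (1 - rj) + f1[, j] * rj
      a1 <- f0[, j] * rj + f1[, j] * (1 - rj)
      f0[, j + 1L] <- a0 * e0[, j + 1L]
      f1[, j + 1L] <- a1 * e1[, j + 1L]
      sc <- f0[, j + 1L] + f1[, j + 1L]
      f0[, j + 1L] <- f0[, j + 1L] / sc; f1[, j + 1L] <- f1[, j + 1L] / sc
    }
    ## backward
    b0 <- matrix(1, n, npos); b1 <- matrix(1, n, npos)
    if (npos > 1L) for (j in (npos - 1L):1L) {
      rj <- r[j]
      t0 <- e0[, j + 1L] * b0[, j + 1L]
      t1 <- e1[, j + 1L] * b1[, j + 1L]
      b0[, j] <- (1 - rj) * t0 + rj * t1
      b1[, j] <- rj * t0 + (1 - rj) * t1
      sc <- b0[, j] + b1[, j]
      b0[, j] <- b0[, j] / sc; b1[, j] <- b1[, j] / sc
    }
    p1 <- f1 * b1 / (f0 * b0 + f1 * b1)
    colnames(p1) <- names(grid$pos)
    out[[ch]] <- list(pos = grid$pos, marker = grid$is_marker, prob = p1)
  }
  structure(out, step = step, error_prob = error_prob, class = "genoprob")
}

## marker grid plus equally spaced pseudomarkers at <= step spacing
grid_positions <- function(mp, step) {
  if (step <= 0) {
    pos <- as.numeric(mp)
    names(pos) <- names(mp)
    return(list(pos = pos, is_marker = rep(TRUE, length(mp)),
                marker_index = seq_along(mp)))
  }
  pos <- as.numeric(mp); nm <- names(mp); is_m <- rep(TRUE, length(mp))
  fill_pos <- numeric(0)
  for (j in seq_len(length(mp) - 1L)) {
    gap <- pos[j + 1L] - pos[j]
    if (gap > step) {
      nfill <- ceiling(gap / step) - 1L
      fill_pos <- c(fill_pos, pos[j] + gap * seq_len(nfill) / (nfill + 1L))
    }
  }
  allpos <- c(pos, fill_pos)
  allnm <- c(nm, sprintf("loc%.1f", fill_pos))
  allm <- c(is_m, rep(FALSE, length(fill_pos)))
  o <- order(allpos)
  pos_sorted <- allpos[o]
  names(pos_sorted) <- allnm[o]
  list(pos = pos_sorted, is_marker = allm[o],
       marker_index = match(seq_along(pos), o))
}

#' @export
print.genoprob <- function(x, ...) {
  cat(sprintf("genoprob: %d chromosomes, %d grid positions, step %g cM, error_prob %g\n",
              length(x), sum(vapply(x, function(ch) length(ch$pos), 0L)),
              attr(x, "step"), attr(x, "error_prob")))
  invisible(x)
}

#' Expected heterozygote dosage at a position
#'
#' The Haley-Knott design column for a single backcross QTL: each
#' individual's probability of carrying the AB genotype at the requested
#' position. Off-grid positions snap to the nearest grid point (reported via
#' the \code{"pos"} attribute).
#'
#' @param probs a \code{genoprob} object.
#' @param chr chromosome name.
#' @param pos position in cM.
#' @return n-vector in [0, 1], attribute \code{pos} = grid position used.
#' @export
dosage <- function(probs, chr, pos) {
  ch <- probs[[as.character(chr)]]
  if (is.null(ch)) stop("unknown chromosome: ", chr)
  j <- which.min(abs(ch$pos - pos))
  structure(ch$prob[, j], pos = unname(ch$pos[j]))
}
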