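#' Haldane map function
#'
#' Converts a genetic map distance in centiMorgans to a recombination
#' fraction assuming crossovers occur as a Poisson process with no
#' interference: \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d Map distance in cM (vectorised, all \code{d >= 0}).
#' @return Recombination fraction(s) in \code{[0, 0.5)}.
#' @examples
#' haldane_r(10)  # ~0.0906
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

# recombination-fraction expansion for selfed RIL (F-infinity)
ril_expand <- function(r) 2 * r / (1 + 2 * r)

# Two-locus genotype transition matrix P(G2 = col | G1 = row) for one
# interval with recombination fraction r, per cross type. BC and DH carry a
# single (doubled) meiotic product; F2 composes two independent gametes;
# RIL applies the selfing expansion r* = 2r/(1+2r) before the BC chain.
cross_transition <- function(r, cross) {
  cross <- cross_type(cross)
  if (cross$name == "RIL") r <- ril_expand(r)
  Tg <- matrix(c(1 - r, r, r, 1 - r), 2L, 2L)
  if (cross$n_classes == 2L) return(Tg)
  # F2: genotype = sum of two gamete states; heterozygote phases equally likely
  Tf <- matrix(0, 3L, 3L)
  cfgs <- list(`0` = list(c(0L, 0L)), `1` = list(c(0L, 1L), c(1L, 0L)),
               `2` = list(c(1L, 1L)))
  for (g1 in 0:2) {
    for (cfg in cfgs[[as.character(g1)]]) {
      w <- 1 / length(cfgs[[as.character(g1)]])
      for (y1 in 0:1) for (y2 in 0:1) {
        p <- Tg[cfg[1] + 1L, y1 + 1L] * Tg[cfg[2] + 1L, y2 + 1L]
        Tf[g1 + 1L, y1 + y2 + 1L] <- Tf[g1 + 1L, y1 + y2 + 1L] + w * p
      }
    }
  }
  Tf
}

#' Build the 1 cM scan grid along a genetic map
#'
#' Positions run from the first to the last marker of each chromosome at
#' \code{step} cM spacing, anchored at the first marker; every marker
#' position is always included, duplicates are removed and positions are
#' sorted. No extrapolation beyond terminal markers.
#'
#' @param map A \code{genetic_map}.
#' @param step Grid spacing in cM (default 1).
#' @return A data frame with columns \code{chr}, \code{pos},
#'   \code{left_marker}, \code{right_marker}, \code{left_pos},
#'   \code{right_pos}; one row per scan position.
#' @export
scan_grid <- function(map, step = 1) {
  map <- as_genetic_map(map)
  stopifnot(step > 0)
  out <- list()
  for (ch in unique(map$chr)) {
    sub <- map[map$chr == ch, , drop = FALSE]
    if (nrow(sub) == 0L) { warning("chromosome ", ch, " has no markers; skipped"); next }
    mpos <- sub$pos_cM
    pos <- sort(unique(c(seq(mpos[1L], mpos[length(mpos)], by = step), mpos)))
    li <- findInterval(pos, mpos)            # index of marker at or before pos
    ri <- ifelse(pos > mpos[li], li + 1L, li)  # strictly inside -> next marker
    out[[ch]] <- data.frame(
      chr = ch, pos = pos,
      left_marker = sub$marker[li], right_marker = sub$marker[ri],
      left_pos = mpos[li], right_pos = mpos[ri],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("map has no markers on any chromosome")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exact three-locus haplotype distribution of a selfed (F-infinity) RIL
# given interval recombination fractions r1, r2. The genotype sequence of
# selfed RILs is NOT a Markov chain over three loci (the per-interval
# Haldane-Waddington expansion r* = 2r/(1+2r) is exact only pairwise), so
# the fixation distribution is computed from the selfing process itself:
# diplotype states iterate offspring = two independent gametes, and the
# chain is solved for its absorption probabilities into the 8 fixed
# haplotypes. Returns a 2 x 2 x 2 array indexed by (left, qtl, right).
ril_joint3 <- function(r1, r2) {
  haps <- as.matrix(expand.grid(a = 0:1, q = 0:1, b = 0:1))[, c(1L, 2L, 3L)]
  gamete_dist <- function(h1, h2, r1, r2) {
    H <- rbind(haps[h1, ], haps[h2, ])
    g <- numeric(8L)
    for (s in 1:2) for (x1 in 0:1) for (x2 in 0:1) {
      p <- 0.5 * (if (x1) r1 else 1 - r1) * (if (x2) r2 else 1 - r2)
      s2 <- if (x1) 3L - s else s
      s3 <- if (x2) 3L - s2 else s2
      al <- c(H[s, 1L], H[s2, 2L], H[s3, 3L])
      idx <- 1L + al[1L] + 2L * al[2L] + 4L * al[3L]
      g[idx] <- g[idx] + p
    }
    g
  }
  # ordered diplotype states (i, j), i, j in 1..8; absorbing when i == j
  Tm <- matrix(0, 64L, 64L)
  for (i in 1:8) for (j in 1:8) {
    g <- gamete_dist(i, j, r1, r2)
    Tm[(i - 1L) * 8L + j, ] <- as.vector(outer(g, g))  # row-major (k, l)
  }
  st <- function(i, j) (i - 1L) * 8L + j
  absorbing <- st(1:8, 1:8)
  transient <- setdiff(1:64, absorbing)
  A <- Tm[transient, transient, drop = FALSE]
  B <- Tm[transient, absorbing, drop = FALSE]
  start <- st(8L, 1L)                     # F1: (1,1,1) over (0,0,0)
  e <- numeric(length(transient))
  e[match(start, transient)] <- 1
  pi_fix <- drop(e %*% solve(diag(length(transient)) - A, B))
  arr <- array(0, c(2L, 2L, 2L))
  for (h in 1:8) arr[haps[h, 1L] + 1L, haps[h, 2L] + 1L, haps[h, 3L] + 1L] <-
    pi_fix[h]
  arr
}

# (J+1) x (J+1) x J lookup of P(QTL class | left code, right code) with
# index J+1 meaning "missing". Markov factorisation for BC/DH/F2; exact
# selfing absorption probabilities for RIL.
cross_lut <- function(cross, r1, r2) {
  J <- cross$n_classes
  lut <- array(NA_real_, dim = c(J + 1L, J + 1L, J))
  prior <- cross$prior
  if (cross$name == "RIL") {
    C3 <- ril_joint3(r1, r2)
    for (ai in 0:J) for (bi in 0:J) {
      p <- if (ai < J && bi < J) C3[ai + 1L, , bi + 1L]
      else if (ai < J) rowSums(C3[ai + 1L, , ])
      else if (bi < J) colSums(C3[, , bi + 1L])
      else apply(C3, 2L, sum)
      s <- sum(p)
      lut[ai + 1L, bi + 1L, ] <- if (s > 0) p / s else prior
    }
    return(lut)
  }
  T1 <- cross_transition(r1, cross)
  T2 <- cross_transition(r2, cross)
  for (ai in 0:J) for (bi in 0:J) {
    p <- if (ai < J && bi < J) T1[ai + 1L, ] * T2[, bi + 1L]
    else if (ai < J) T1[ai + 1L, ]
    else if (bi < J) prior * T2[, bi + 1L]
    else prior
    s <- sum(p)
    lut[ai + 1L, bi + 1L, ] <- if (s > 0) p / s else prior
  }
  lut
}

#' Conditional QTL genotype probabilities at a scan position
#'
#' For each individual, the probability of each putative QTL genotype class
#' given the observed genotypes at the flanking markers, under the Haldane
#' (no-interference) model appropriate to the cross type. BC/DH/F2 use the
#' two-interval Markov factorisation; selfed RIL probabilities come from
#' the exact fixation distribution of the selfing process (the pairwise
#' expansion \eqn{r^* = 2r/(1+2r)} is not exact over three loci). At a
#' typed marker
#' the row is the indicator of the observed class; individuals missing one
#' flanking genotype condition on the other side only; individuals missing
#' both fall back to the cross's population prior.
#'
#' @param pos A single row of \code{\link{scan_grid}} (or a list with fields
#'   \code{chr}, \code{pos}, \code{left_marker}, \code{right_marker},
#'   \code{left_pos}, \code{right_pos}).
#' @param geno A genotype matrix component of an \code{fm_dataset} (list with
#'   \code{ids} and integer \code{codes} matrix, columns named by marker).
#' @param map A \code{genetic_map} (used only for validation).
#' @param cross A \code{cross_type} or its name.
#' @return An \code{n x J} row-stochastic matrix of probabilities.
#' @export
conditional_probs <- function(pos, geno, map, cross) {
  cross <- cross_type(cross)
  J <- cross$n_classes
  if (is.data.frame(pos)) pos <- as.list(pos[1L, ])
  if (pos$pos < pos$left_pos - 1e-9 || pos$pos > pos$right_pos + 1e-9)
    stop("scan position ", pos$pos, " lies outside its marker interval")
  a <- geno$codes[, pos$left_marker]
  b <- geno$codes[, pos$right_marker]
  r1 <- haldane_r(max(pos$pos - pos$left_pos, 0))
  r2 <- haldane_r(max(pos$right_pos - pos$pos, 0))
  lut <- cross_lut(cross, r1, r2)
  ai <- ifelse(is.na(a), J, a)
  bi <- ifelse(is.na(b), J, b)
  out <- matrix(NA_real_, length(ai), J)
  for (j in seq_len(J)) out[, j] <- lut[cbind(ai + 1L, bi + 1L, j)]
  out
}
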