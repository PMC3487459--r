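#' Genotype space for L biallelic loci
#'
#' Builds the set of all `2^L` haploid genotypes over `L` biallelic loci,
#' together with the single-mutation neighbourhood structure used by both the
#' deterministic and the stochastic model. Alleles are coded 0 (deleterious)
#' and 1 (beneficial). Genotype `g` is the integer in `[0, 2^L)` whose bit `b`
#' (bit 0 = least significant) holds the allele at locus `b`; the string
#' rendering is most-significant-bit first, so `"1111"` is the global peak and
#' `"0000"` the least fit genotype.
#'
#' @param L integer number of loci, at least 2.
#' @return An object of class `genotype_space`: a list with elements
#'   `L`, `n` (`2^L`), `genotypes` (character vector of binary strings, in
#'   index order `0 .. 2^L - 1`), `k` (integer vector, number of 0-alleles of
#'   each genotype), `neighbors` (`n x L` integer matrix of 1-based genotype
#'   indices at Hamming distance one; column `l` flips locus `l - 1`),
#'   `alleles` (`n x L` 0/1 matrix, column `l` = allele at locus `l - 1`),
#'   `peak` (1-based index of the all-1 genotype) and `origin` (1-based index
#'   of the all-0 genotype).
#' @examples
#' gs <- genotype_space(2)
#' gs$genotypes      # "00" "01" "10" "11"
#' gs$k              # 2 1 1 0
#' @seealso [hamming_distance()], [build_landscape()]
#' @export
genotype_space <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L)
    stop("L must be an integer >= 2", call. = FALSE)
  if (L > 20L)
    stop("L > 20 is not supported (2^L genotypes would be enumerated)", call. = FALSE)
  n <- 2L^L
  idx <- 0:(n - 1L)
  alleles <- matrix(0L, n, L)
  for (l in seq_len(L)) alleles[, l] <- bitwAnd(bitwShiftR(idx, l - 1L), 1L)
  k <- as.integer(L - rowSums(alleles))
  neighbors <- matrix(0L, n, L)
  for (l in seq_len(L)) neighbors[, l] <- bitwXor(idx, bitwShiftL(1L, l - 1L)) + 1L
  genotypes <- vapply(idx, genotype_string, character(1), L = L)
  structure(
    list(L = L, n = n, genotypes = genotypes, k = k,
         neighbors = neighbors, alleles = alleles,
         peak = n, origin = 1L),
    class = "genotype_space"
  )
}

#' @export
print.genotype_space <- function(x, ...) {
  cat("Genotype space: L =", x$L, "loci,", x$n, "genotypes\n")
  invisible(x)
}

#' Render a genotype index as a binary string
#'
#' Most-significant-bit first: locus `L - 1` is the leftmost character.
#'
#' @param g integer genotype index (0-based) or vector thereof.
#' @param L number of loci.
#' @return character vector of `L`-character binary strings.
#' @export
genotype_string <- function(g, L) {
  vapply(g, function(gi) {
    bits <- bitwAnd(bitwShiftR(gi, (L - 1L):0L), 1L)
    paste(bits, collapse = "")
  }, character(1))
}

#' Parse genotype strings into 0-based indices
#'
#' @param s character vector of binary strings (most-significant-bit first).
#' @param L number of loci; defaults to the string width.
#' @return integer vector of genotype indices in `[0, 2^L)`.
#' @export
genotype_index <- function(s, L = nchar(s[1])) {
  if (any(nchar(s) != L)) stop("genotype strings must have width L", call. = FALSE)
  if (any(!grepl("^[01]+$", s))) stop("genotype strings must be binary", call. = FALSE)
  vapply(s, function(si) {
    bits <- as.integer(strsplit(si, "")[[1]])
    as.integer(sum(bits * 2L^((L - 1L):0L)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Hamming distance between genotypes
#'
#' @param g1,g2 0-based integer genotype indices (vectorized).
#' @return integer vector of Hamming distances.
#' @export
hamming_distance <- function(g1, g2) {
  x <- bitwXor(as.integer(g1), as.integer(g2))
  d <- integer(length(x))
  while (any(x > 0L)) {
    d <- d + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  d
}

#' Define a fitness topography (a configuration of LFGs)
#'
#' A fitness topography is the set of intermediate genotypes designated as
#' low-fitness genotypes (LFGs, relative Malthusian fitness 0). The all-0 and
#' all-1 genotypes are never LFGs.
#'
#' @param L number of loci.
#' @param lfgs LFG genotypes, as 0-based integer indices or as binary strings
#'   (e.g. `"0101"`). May be empty.
#' @return An object of class `fitness_topography`: list with `L`,
#'   `lfgs` (sorted 0-based integer indices) and `id` (a stable string label,
#'   `"<L>:g+g+..."`).
#' @examples
#' fitness_topography(2, c("01", "10"))   # the reciprocal-sign-epistasis valley
#' @export
fitness_topography <- function(L, lfgs = integer(0)) {
  L <- as.integer(L)
  if (is.character(lfgs)) lfgs <- genotype_index(lfgs, L)
  lfgs <- sort(unique(as.integer(lfgs)))
  n <- 2L^L
  if (length(lfgs) && (min(lfgs) < 0L || max(lfgs) >= n))
    stop("LFG indices must lie in [0, 2^L)", call. = FALSE)
  if (any(lfgs == 0L) || any(lfgs == n - 1L))
    stop("the all-0 and all-1 genotypes cannot be LFGs", call. = FALSE)
  structure(
    list(L = L, lfgs = lfgs, id = topography_id(L, lfgs)),
    class = "fitness_topography"
  )
}

topography_id <- function(L, lfgs) {
  if (!length(lfgs)) return(paste0(L, ":none"))
  paste0(L, ":", paste(genotype_string(lfgs, L), collapse = "+"))
}

#' @export
print.fitness_topography <- function(x, ...) {
  cat("Fitness topography: L =", x$L, "|", length(x$lfgs), "LFG(s)")
  if (length(x$lfgs)) cat(":", paste(genotype_string(x$lfgs, x$L), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Basal (smooth) Malthusian fitness
#'
#' Fitness of a genotype carrying `k` deleterious (0) alleles on the smooth
#' single-peaked baseline landscape: `m(k) = 1 - s * k^eps`. `s` is the
#' reduction in Malthusian fitness per deleterious allele; `eps` tunes
#' one-dimensional magnitude epistasis (`eps = 1` additive; `eps > 1`
#' antagonistic beneficial mutations, i.e. intermediates lower than additive;
#' `eps < 1` synergistic beneficial mutations).
#'
#' @param k integer count(s) of deleterious alleles.
#' @param s selection coefficient, `s > 0`.
#' @param eps epistasis exponent, `eps > 0`.
#' @return numeric vector of Malthusian fitness values in `[0, 1]`.
#' @export
basal_fitness <- function(k, s, eps) {
  if (any(k < 0) || any(k != floor(k)))
    stop("k must be a non-negative integer", call. = FALSE)
  if (s <= 0) stop("s must be positive", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  m <- 1 - s * k^eps
  if (any(m < 0)) {
    bad <- k[which(m < 0)[1]]
    stop(sprintf("negative fitness at k = %d (s * k^eps = %.4g > 1); reduce s or eps",
                 bad, s * bad^eps), call. = FALSE)
  }
  m
}

#' Build a fitness landscape from a baseline and a topography
#'
#' Overlays a set of low-fitness genotypes (Malthusian fitness 0) on the
#' smooth baseline `m(k) = 1 - s * k^eps`, where `k` counts the 0-alleles of a
#' genotype. The all-1 genotype always has fitness 1.
#'
#' @param space a [genotype_space()], or an integer `L` (the space is built).
#' @param s selection coefficient.
#' @param eps baseline epistasis exponent.
#' @param topography a [fitness_topography()]; defaults to no LFGs.
#' @return An object of class `fitness_landscape`: list with `space`, `s`,
#'   `eps`, `topography` and `m` (numeric vector of Malthusian fitness, one
#'   entry per genotype in index order).
#' @examples
#' build_landscape(2, s = 0.05, eps = 1,
#'                 topography = fitness_topography(2, c("01", "10")))
#' @export
build_landscape <- function(space, s, eps, topography = NULL) {
  if (!inherits(space, "genotype_space")) space <- genotype_space(space)
  if (is.null(topography)) topography <- fitness_topography(space$L)
  if (!inherits(topography, "fitness_topography"))
    stop("topography must be a fitness_topography", call. = FALSE)
  if (topography$L != space$L)
    stop("topography and genotype space disagree on L", call. = FALSE)
  m <- basal_fitness(space$k, s, eps)
  m[topography$lfgs + 1L] <- 0
  structure(
    list(space = space, s = s, eps = eps, topography = topography, m = m),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("Fitness landscape: L =", x$space$L,
      "| s =", x$s, "| eps =", x$eps,
      "|", length(x$topography$lfgs), "LFG(s)\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.fitness_landscape <- function(x, ...) {
  data.frame(
    genotype = x$space$genotypes,
    k = x$space$k,
    is_lfg = seq_len(x$space$n) %in% (x$topography$lfgs + 1L),
    m = x$m,
    stringsAsFactors = FALSE
  )
}

#' Enumerate all fitness topographies with up to a given number of LFGs
#'
#' Yields every subset of the `2^L - 2` intermediate genotypes with
#' cardinality at most `max_lfgs`, each exactly once, ordered by cardinality
#' and then lexicographically by the sorted genotype-index tuple. The order is
#' deterministic, so screens over the enumeration are reproducible and
#' resumable.
#'
#' @param L number of loci.
#' @param max_lfgs maximum number of LFGs, `0 <= max_lfgs <= 2^L - 2`.
#' @param sizes optional integer vector restricting the LFG counts emitted
#'   (subset of `0:max_lfgs`); default all of `0:max_lfgs`.
#' @return list of [fitness_topography()] objects.
#' @examples
#' length(enumerate_topographies(2, 2))   # 4
#' @export
enumerate_topographies <- function(L, max_lfgs, sizes = NULL) {
  L <- as.integer(L)
  n_int <- 2L^L - 2L
  if (max_lfgs < 0 || max_lfgs > n_int)
    stop("max_lfgs must lie in [0, 2^L - 2]", call. = FALSE)
  intermediates <- seq_len(n_int)  # genotype indices 1 .. 2^L - 2
  if (is.null(sizes)) sizes <- 0:max_lfgs
  out <- list()
  for (j in sizes) {
    if (j == 0L) {
      out[[length(out) + 1L]] <- fitness_topography(L)
      next
    }
    sets <- utils::combn(intermediates, j, simplify = FALSE)
    # combn over a sorted vector is already lexicographic in the sorted tuple
    for (ss in sets) out[[length(out) + 1L]] <- fitness_topography(L, ss)
  }
  out
}

#' Number of topographies with up to a given number of LFGs
#'
#' `sum_{j=0..max_lfgs} choose(2^L - 2, j)`.
#'
#' @inheritParams enumerate_topographies
#' @return a number.
#' @export
count_topographies <- function(L, max_lfgs) {
  sum(choose(2^L - 2, 0:max_lfgs))
}

# Apply a locus permutation to genotype indices: perm[l] gives the new locus
# (1-based positions over loci 0..L-1) receiving the allele of old locus l.
permute_loci <- function(g, perm, L) {
  out <- integer(length(g))
  for (l in seq_len(L)) {
    bit <- bitwAnd(bitwShiftR(as.integer(g), l - 1L), 1L)
    out <- bitwOr(out, bitwShiftL(bit, perm[l] - 1L))
  }
  out
}

all_permutations <- function(L) {
  if (L == 1L) return(list(1L))
  sub <- all_permutations(L - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(L))
      out[[length(out) + 1L]] <- append(p, L, after = pos - 1L)
  out
}

canonical_topography_key <- function(lfgs, perms, L) {
  if (!length(lfgs)) return("none")
  best <- NULL
  for (p in perms) {
    cand <- sort(permute_loci(lfgs, p, L))
    if (is.null(best)) best <- cand
    else {
      cmp <- cand - best
      nz <- which(cmp != 0)
      if (length(nz) && cmp[nz[1]] < 0) best <- cand
    }
  }
  paste(best, collapse = ",")
}

#' Partition topographies into locus-permutation equivalence classes
#'
#' Two topographies are equivalent when some permutation of locus positions
#' maps one LFG set onto the other. Equivalent landscapes have identical
#' dynamics (and hence identical `T_fix`) under any locus-symmetric parameter
#' set, so screens need only visit one representative per class.
#'
#' @param topographies list of [fitness_topography()] objects sharing `L`.
#' @return list of classes; each class is a list with `representative` (the
#'   lexicographically least member), `members` (integer indices into the
#'   input list) and `size` (class cardinality).
#' @examples
#' cls <- orbit_classes(enumerate_topographies(2, 2))
#' length(cls)   # 3
#' @export
orbit_classes <- function(topographies) {
  if (!length(topographies)) return(list())
  L <- topographies[[1]]$L
  if (!all(vapply(topographies, function(t) t$L, integer(1)) == L))
    stop("all topographies must share L", call. = FALSE)
  perms <- all_permutations(L)
  keys <- vapply(topographies, function(t)
    canonical_topography_key(t$lfgs, perms, L), character(1))
  groups <- split(seq_along(topographies), keys)
  out <- lapply(groups, function(members) {
    # representative: lexicographically least LFG tuple among members
    reps <- topographies[members]
    ord <- order(vapply(reps, function(t)
      paste(sprintf("%06d", t$lfgs), collapse = ","), character(1)))
    list(representative = reps[[ord[1]]],
         members = members,
         size = length(members))
  })
  names(out) <- NULL
  # stable order: by size of LFG set, then by representative id
  ord <- order(vapply(out, function(cl) length(cl$representative$lfgs), integer(1)),
               vapply(out, function(cl) cl$representative$id, character(1)))
  out[ord]
}

#' Orbit representatives of all topographies with exactly n LFGs
#'
#' Convenience wrapper: enumerates every topography with `n_lfgs` LFGs and
#' returns one representative per locus-permutation class, with class sizes.
#'
#' @param L number of loci.
#' @param n_lfgs exact LFG count (scalar or vector of counts).
#' @return list with `topographies` (representatives) and `sizes`
#'   (integer class cardinalities, summing to the total count).
#' @export
orbit_representatives <- function(L, n_lfgs) {
  topos <- enumerate_topographies(L, max(n_lfgs), sizes = n_lfgs)
  cls <- orbit_classes(topos)
  list(topographies = lapply(cls, `[[`, "representative"),
       sizes = vapply(cls, `[[`, integer(1), "size"))
}

#' Sample fitness topographies uniformly at random
#'
#' Uniform sampling without replacement among all topographies with exactly
#' `n_lfgs` LFGs.
#'
#' @param L number of loci.
#' @param n_lfgs exact number of LFGs per topography.
#' @param count number of topographies to draw; must not exceed
#'   `choose(2^L - 2, n_lfgs)`.
#' @param seed optional integer seed (local to this call; the caller's RNG
#'   state is untouched).
#' @return list of [fitness_topography()] objects.
#' @export
sample_topographies <- function(L, n_lfgs, count, seed = NULL) {
  n_int <- 2L^L - 2L
  total <- choose(n_int, n_lfgs)
  if (count > total)
    stop(sprintf("count = %d exceeds the %g available topographies", count, total),
         call. = FALSE)
  draw <- function() {
    if (total <= 2e6) {
      sets <- utils::combn(seq_len(n_int), n_lfgs, simplify = FALSE)
      sets[sample.int(length(sets), count)]
    } else {
      seen <- new.env(hash = TRUE)
      out <- vector("list", count)
      got <- 0L
      while (got < count) {
        cand <- sort(sample.int(n_int, n_lfgs))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- cand
        }
      }
      out
    }
  }
  sets <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  lapply(sets, function(ss) fitness_topography(L, ss))
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
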