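# Independent oracles used by the property tests. These deliberately share
# no code with the package implementation.

# Brute-force ROH scan: enumerate every candidate run [i, j], accept it if
# all bins qualify, it is long enough, and it is maximal.
brute_force_runs <- function(qual, retained, min_bins) {
  n <- length(qual)
  ok <- qual & retained
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 < min_bins) next
    if (!all(ok[i:j])) next
    left_open <- i == 1 || !ok[i - 1]
    right_open <- j == n || !ok[j + 1]
    if (left_open && right_open) out[[length(out) + 1]] <- c(i, j)
  }
  if (length(out) == 0)
    return(data.frame(first = integer(), last = integer()))
  m <- do.call(rbind, out)
  data.frame(first = m[, 1], last = m[, 2])
}

# Wright's path-counting inbreeding coefficient. F(X) sums, over every
# common ancestor A of X's parents and every pair of ancestor paths meeting
# only at A, (1/2)^(n1+n2+1) * (1 + F(A)).
wright_F <- function(ped, id) {
  parents <- function(i) {
    k <- match(i, ped$id)
    p <- c(ped$sire[k], ped$dam[k])
    p[p != "WILD"]
  }
  # all ancestor paths from `from` (inclusive) upwards, as id vectors
  paths_up <- function(from) {
    out <- list(from)
    for (p in parents(from))
      for (pp in paths_up(p)) out[[length(out) + 1]] <- c(from, pp)
    out
  }
  f_of <- function(x) {
    k <- match(x, ped$id)
    s <- ped$sire[k]; d <- ped$dam[k]
    if (s == "WILD" || d == "WILD") return(0)
    total <- 0
    for (p1 in paths_up(s)) for (p2 in paths_up(d)) {
      a <- p1[length(p1)]
      if (a != p2[length(p2)]) next
      shared <- intersect(p1, p2)
      if (length(shared) != 1) next            # paths must meet only at A
      n1 <- length(p1) - 1; n2 <- length(p2) - 1
      total <- total + 0.5^(n1 + n2 + 1) * (1 + f_of(a))
    }
    total
  }
  f_of(id)
}

# A random pedigree: founders plus individuals whose parents are drawn from
# earlier individuals (or WILD), acyclic by construction.
random_pedigree <- function(n, n_founders = 4, seed = 1) {
  set.seed(seed)
  id <- paste0("I", seq_len(n))
  sire <- dam <- rep("WILD", n)
  for (i in (n_founders + 1):n) {
    pool <- id[seq_len(i - 1)]
    sire[i] <- sample(c(pool, "WILD"), 1)
    dam[i] <- sample(c(pool, "WILD"), 1)
    if (sire[i] == dam[i] && sire[i] != "WILD") dam[i] <- "WILD"
  }
  data.frame(id = id, sire = sire, dam = dam,
             birth_date = NA_character_, stringsAsFactors = FALSE)
}

# Tiny variant table builder for unit tests: gt is a site-by-sample matrix.
vt <- function(gt, dp = NULL, chrom = "chr1", pos = NULL) {
  gt <- as.matrix(gt)
  if (is.null(colnames(gt))) colnames(gt) <- paste0("S", seq_len(ncol(gt)))
  if (is.null(pos)) pos <- seq_len(nrow(gt)) * 100L
  variant_table(
    data.frame(chrom = rep(chrom, nrow(gt)), pos = pos,
               ref = rep("A", nrow(gt)), alt = rep("C", nrow(gt)),
               stringsAsFactors = FALSE),
    gt, dp)
}

# Minimal bin track builder: scaled counts given directly, full coverage.
bt <- function(scaled, chrom = "chr1", covered = 10000L,
               retained = NULL, bin_size = 10000L) {
  n <- length(scaled)
  covered <- rep_len(covered, n)
  track <- data.frame(
    chrom = rep_len(chrom, n),
    start = (seq_len(n) - 1L) * bin_size,
    end = seq_len(n) * bin_size,
    covered_sites = covered,
    raw_snp_count = as.integer(round(scaled * covered / bin_size)),
    scaled_snp_count = scaled,
    retained = if (is.null(retained)) covered > 0 else retained)
  attr(track, "bin_size") <- bin_size
  track
}
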