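# Independent oracles and small fixture builders used across tests.

GC <- Biostrings::GENETIC_CODE

# exhaustive pathway enumeration for one codon pair, written independently
# of the package implementation: walk every permutation of the differing
# positions, drop walks through stop codons, average (nd, sd)
oracle_pair_counts <- function(a, b) {
  pa <- strsplit(a, "")[[1]]
  pb <- strsplit(b, "")[[1]]
  diffs <- which(pa != pb)
  if (length(diffs) == 0) return(c(nd = 0, sd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  walks <- list()
  for (ord in perms(diffs)) {
    cur <- pa
    nd <- 0; sd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- pb[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (GC[c2] == "*" && c2 != b) { blocked <- TRUE; break }
      if (GC[c1] == GC[c2]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) walks[[length(walks) + 1]] <- c(nd = nd, sd = sd)
  }
  if (length(walks) == 0) return(NULL)
  colMeans(do.call(rbind, walks))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  obs <- u_of(x, y)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= obs + 1e-9)
  p_ge <- mean(us >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# genotype-matrix fixture: explicit codes (rows = sites x samples)
make_gm <- function(codes, chrom = "chr1", pos = NULL, ref = "A", alt = "G",
                    samples = NULL, depth = NULL) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(codes)))
  colnames(codes) <- samples
  genotype_matrix(
    data.frame(chrom = rep_len(chrom, n), pos = pos,
               ref = rep(ref, length.out = n), alt = rep(alt, length.out = n),
               stringsAsFactors = FALSE),
    matrix(as.integer(codes), n, ncol(codes), dimnames = list(NULL, samples)),
    depth)
}

# constant-depth coverage track (bin_size 1 gives per-position semantics)
make_const_track <- function(samples, chrom_lengths, depth = 50, bin_size = 1,
                             library_size = 1e6) {
  d <- lapply(samples, function(s)
    lapply(chrom_lengths, function(len) rep(depth, ceiling(len / bin_size))))
  names(d) <- samples
  coverage_track(d, bin_size, chrom_lengths,
                 stats::setNames(rep(library_size, length(samples)), samples))
}

# small simulated dataset reused by several test files
tiny_dataset <- function(seed = 11) {
  cfg <- sim_config(n_autosomes = 6, autosome_length = 4e5,
                    anc_sex = list(length = 8e5, deleted_span = c(2e5, 4.4e5)),
                    neo_sex = list(length = 8e5, decay_scale = 3e5),
                    genes = list(per_chrom = 2), seed = seed)
  simulate_dataset(cfg)
}

roles_of <- function(ds) sample_roles(ds$sample_sheet, "focal", "sister", "outgroup")
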