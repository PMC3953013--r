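# Precomputed codon lookup tables for Nei-Gojobori (NG86) counting.
#
# Conventions (standard genetic code):
#  * per-codon synonymous site count s = sum over the 3 positions of
#    (number of synonymous single-nucleotide changes) / 3; changes producing
#    stop codons count as nonsynonymous, so s + n = 3 for every sense codon.
#  * for a codon pair differing at k positions, (Nd, Sd) are averaged over
#    the k! orderings of single-nucleotide steps, excluding orderings that
#    pass through a stop codon (if every ordering is blocked, all orderings
#    are used as a fallback; this cannot happen for k <= 2 sense pairs).

.codon_cache <- new.env(parent = emptyenv())

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

is_stop_codon <- function(codon) codon_aa(codon) == "*"

#' Synonymous site counts per codon
#'
#' Number of synonymous sites (0 to 3) for each of the 64 codons, with
#' mutations to stop codons counted as nonsynonymous. Stop codons map to NA.
#'
#' @return named numeric vector of length 64.
#' @export
codon_syn_sites <- function() {
  if (!is.null(.codon_cache$syn_sites)) return(.codon_cache$syn_sites)
  codons <- all_codons()
  gc <- Biostrings::GENETIC_CODE
  bases <- c("T", "C", "A", "G")
  s <- vapply(codons, function(cod) {
    if (gc[cod] == "*") return(NA_real_)
    tot <- 0
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      for (b in setdiff(bases, ref)) {
        alt <- cod
        substr(alt, p, p) <- b
        if (gc[alt] != "*" && gc[alt] == gc[cod]) tot <- tot + 1
      }
    }
    tot / 3
  }, numeric(1))
  names(s) <- codons
  .codon_cache$syn_sites <- s
  s
}

# (Nd, Sd) for one ordered path through the differing positions
.path_counts <- function(from, to, order, gc) {
  nd <- 0; sd <- 0
  cur <- from
  for (p in order) {
    nxt <- cur
    substr(nxt, p, p) <- substr(to, p, p)
    if (gc[nxt] == "*" && nxt != to) return(NULL) # path through a stop
    if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
    cur <- nxt
  }
  c(nd = nd, sd = sd)
}

# pathway-averaged (Nd, Sd) for a single codon pair (both sense codons)
codon_pair_path_counts <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0) return(c(nd = 0, sd = 0))
  orders <- switch(as.character(length(diffs)),
                   "1" = list(diffs),
                   "2" = list(diffs, rev(diffs)),
                   "3" = {
                     pm <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
                     lapply(seq_len(6), function(i) diffs[pm[i, ]])
                   })
  counts <- Filter(Negate(is.null), lapply(orders, .path_counts, from = a, to = b, gc = gc))
  if (length(counts) == 0) { # all paths blocked by stops: fall back to all orderings
    counts <- lapply(orders, function(o) {
      nd <- 0; sd <- 0; cur <- a
      for (p in o) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd = nd, sd = sd)
    })
  }
  m <- do.call(rbind, counts)
  c(nd = mean(m[, "nd"]), sd = mean(m[, "sd"]))
}

# per-codon single-change classification: for each sense codon, the 9
# (position, alternative-base) changes with their effect class
# ("synonymous" / "nonsynonymous" / "stop"); returned as 64 x 9 matrices
codon_change_classes <- function() {
  if (!is.null(.codon_cache$chg)) return(.codon_cache$chg)
  codons <- all_codons()
  gc <- Biostrings::GENETIC_CODE
  off <- rep(1:3, each = 3)
  eff <- matrix(NA_character_, 64, 9, dimnames = list(codons, NULL))
  alt <- matrix(NA_character_, 64, 9, dimnames = list(codons, NULL))
  for (cod in codons) {
    if (gc[cod] == "*") next
    j <- 0
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      for (b in setdiff(c("T", "C", "A", "G"), ref)) {
        j <- j + 1
        nc <- cod
        substr(nc, p, p) <- b
        alt[cod, j] <- b
        eff[cod, j] <- if (gc[nc] == "*") "stop"
        else if (gc[nc] == gc[cod]) "synonymous" else "nonsynonymous"
      }
    }
  }
  .codon_cache$chg <- list(eff = eff, alt = alt, off = off)
  .codon_cache$chg
}

#' Pathway-averaged substitution counts for all codon pairs
#'
#' 64 x 64 matrices of nonsynonymous (`nd`) and synonymous (`sd`)
#' differences per codon pair, averaged over mutational pathways with
#' stop-codon intermediates excluded. Pairs involving a stop codon are NA.
#'
#' @return list with matrices `nd` and `sd` (dimnames = codons).
#' @export
codon_pair_counts <- function() {
  if (!is.null(.codon_cache$pair)) return(.codon_cache$pair)
  codons <- all_codons()
  gc <- Biostrings::GENETIC_CODE
  n <- length(codons)
  nd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  sd <- nd
  sense <- codons[gc[codons] != "*"]
  for (a in sense) for (b in sense) {
    if (a == b) { nd[a, b] <- 0; sd[a, b] <- 0; next }
    cc <- codon_pair_path_counts(a, b)
    nd[a, b] <- cc["nd"]; sd[a, b] <- cc["sd"]
  }
  .codon_cache$pair <- list(nd = nd, sd = sd)
  .codon_cache$pair
}
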