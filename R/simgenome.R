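# Synthetic genomes, genotypes, coverage, gene models and expression with
# known per-site truth, emulating a two-species design in which the focal
# species carries a Y-autosome fusion (a neo-sex chromosome) and both
# species share a degenerate ancestral Y.

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 5 focal males, 5 focal females, 1 sister-species male, 5 sister-species
#' females and 1 outgroup female; 20 autosomes (2 Mb each, scaled down from
#' ~20 Mb chromosomes); a 20-Mb ancestral sex chromosome whose Y has lost a
#' 6-Mb span (male depth factor 0.5); an 18-Mb neo-sex chromosome whose
#' X-Y heterozygosity decays from `p_max` = 0.01 at the fusion end with an
#' exponential scale of 5 Mb; per-bp rates of 5e-4 for fixed inter-species
#' differences and within-species polymorphism (focal polymorphism on the
#' neo-sex chromosome reduced by `focal_poly_factor`), 5e-3 for outgroup
#' divergence; and read depth averaging 50x.
#'
#' @param n_autosomes,autosome_length autosome count and length (bp).
#' @param anc_sex list: `length`, `deleted_span` (c(start, end)),
#'   `male_depth_factor`, `xy_het_rate`.
#' @param neo_sex list: `length`, `fusion_end`, `p_max`, `decay_scale`,
#'   `decay` ("exponential" or "logistic"), `x_fraction`,
#'   `focal_poly_factor`, `coding_omega` (named: X_specific, Y_specific,
#'   shared).
#' @param species list: `fixed_diff_rate`, `polymorphism_rate`,
#'   `outgroup_divergence_rate`, `background_omega`.
#' @param samples list of counts: `focal_males`, `focal_females`,
#'   `other_males`, `other_females`, `outgroup_females`.
#' @param depth list: `mean`, `dispersion` (gamma shape), `bin_size`,
#'   `zero_bin_rate` (fraction of repeat-masked bins).
#' @param genes list: `per_chrom`, `codon_range` (min/max codons).
#' @param expression list: `n_reps`, `sd_log2`, `biased_fraction_autosome`,
#'   `biased_fraction_neo`, `effect_log2`, `cis_coupling` (log2 expression
#'   shift per expected upstream X-Y heterozygous site).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_autosomes = 20,
                       autosome_length = 2e6,
                       anc_sex = list(),
                       neo_sex = list(),
                       species = list(),
                       samples = list(),
                       depth = list(),
                       genes = list(),
                       expression = list(),
                       seed = 1L) {
  merge_def <- function(given, def) { def[names(given)] <- given; def }
  cfg <- list(
    n_autosomes = n_autosomes,
    autosome_length = autosome_length,
    anc_sex = merge_def(anc_sex, list(length = 20e6, deleted_span = c(6e6, 12e6),
                                      male_depth_factor = 0.5, xy_het_rate = 0.004)),
    neo_sex = merge_def(neo_sex, list(length = 18e6, fusion_end = 1,
                                      p_max = 0.01, decay_scale = 5e6,
                                      decay = "exponential", x_fraction = 0.5,
                                      focal_poly_factor = 0.4,
                                      coding_omega = c(X_specific = 0.2,
                                                       Y_specific = 0.35,
                                                       shared = 0.2))),
    species = merge_def(species, list(fixed_diff_rate = 5e-4,
                                      polymorphism_rate = 5e-4,
                                      outgroup_divergence_rate = 5e-3,
                                      background_omega = 0.2)),
    samples = merge_def(samples, list(focal_males = 5, focal_females = 5,
                                      other_males = 1, other_females = 5,
                                      outgroup_females = 1)),
    depth = merge_def(depth, list(mean = 50, dispersion = 20, bin_size = 1e4,
                                  zero_bin_rate = 0.02)),
    genes = merge_def(genes, list(per_chrom = 20, codon_range = c(150, 400))),
    expression = merge_def(expression, list(n_reps = 4, sd_log2 = 0.5,
                                            biased_fraction_autosome = 0.05,
                                            biased_fraction_neo = 0.15,
                                            effect_log2 = 2, cis_coupling = 0.02)),
    seed = as.integer(seed))
  stopifnot(cfg$species$fixed_diff_rate >= 0, cfg$species$fixed_diff_rate <= 1,
            cfg$neo_sex$p_max >= 0, cfg$neo_sex$p_max <= 1,
            cfg$anc_sex$deleted_span[1] >= 1,
            cfg$anc_sex$deleted_span[2] <= cfg$anc_sex$length)
  class(cfg) <- "sim_config"
  cfg
}

sim_sample_sheet <- function(cfg) {
  s <- cfg$samples
  data.frame(
    sample_id = c(sprintf("FM%d", seq_len(s$focal_males)),
                  sprintf("FF%d", seq_len(s$focal_females)),
                  sprintf("SM%d", seq_len(s$other_males)),
                  sprintf("SF%d", seq_len(s$other_females)),
                  sprintf("OG%d", seq_len(s$outgroup_females))),
    species = c(rep("focal", s$focal_males + s$focal_females),
                rep("sister", s$other_males + s$other_females),
                rep("outgroup", s$outgroup_females)),
    sex = c(rep("male", s$focal_males), rep("female", s$focal_females),
            rep("male", s$other_males), rep("female", s$other_females),
            rep("female", s$outgroup_females)),
    stringsAsFactors = FALSE)
}

#' Random open reading frame
#'
#' ATG followed by random sense codons (no internal stops).
#'
#' @param n_codons total codon count (>= 2).
#' @param seed optional seed.
#' @return character CDS of length 3 * n_codons.
#' @export
random_orf <- function(n_codons, seed = NULL) {
  with_local_seed(seed, {
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
  })
}

# enumerate a gene's candidate single-nucleotide changes by effect class
# (stop-creating changes excluded) and its genomic CDS coordinate map
.gene_change_lists <- function(gene) {
  chg <- codon_change_classes()
  cods <- split_codons(gene$cds_seq)
  m <- length(cods)
  E <- chg$eff[cods, , drop = FALSE]
  A <- chg$alt[cods, , drop = FALSE]
  P <- rep(3L * (seq_len(m) - 1L), times = 9) + rep(chg$off, each = m)
  gene$syn_changes <- data.frame(cds_pos = P[E == "synonymous"],
                                 alt = A[E == "synonymous"],
                                 stringsAsFactors = FALSE)
  gene$nonsyn_changes <- data.frame(cds_pos = P[E == "nonsynonymous"],
                                    alt = A[E == "nonsynonymous"],
                                    stringsAsFactors = FALSE)
  cds_map <- sort(unlist(Map(seq.int, gene$cds$start, gene$cds$end)))
  if (identical(gene$strand, "-")) cds_map <- rev(cds_map)
  gene$cds_map <- cds_map
  gene
}

# place gene models on one chromosome; returns list of gene models
.sim_genes_for_chrom <- function(chrom, len, cfg) {
  n <- cfg$genes$per_chrom
  out <- list()
  occupied <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    n_cod <- sample(seq(cfg$genes$codon_range[1], cfg$genes$codon_range[2]), 1)
    cds_len <- 3 * n_cod
    n_ex <- sample(1:3, 1)
    cuts <- sort(sample(seq_len(n_cod - 1), n_ex - 1)) * 3
    ex_lens <- diff(c(0, cuts, cds_len))
    introns <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE) else integer(0)
    span <- sum(ex_lens) + sum(introns)
    placed <- FALSE
    for (try in 1:50) {
      start <- sample.int(max(1, len - span - 2000), 1) + 1000
      endp <- start + span - 1
      if (nrow(occupied) == 0 ||
          all(endp < occupied[, 1] - 1000 | start > occupied[, 2] + 1000)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) next
    occupied <- rbind(occupied, c(start, endp))
    st <- start + cumsum(c(0, (ex_lens + c(introns, 0))[-n_ex]))
    en <- st + ex_lens - 1
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("%s_g%d", chrom, k)
    out[[gid]] <- .gene_change_lists(
      list(gene_id = gid, chrom = chrom, strand = strand,
           cds = data.frame(start = st, end = en),
           cds_seq = random_orf(n_cod)))
  }
  out
}

# genomic-position -> CDS-position resolver for a set of genes on one chrom
.cds_resolver <- function(genes) {
  if (length(genes) == 0)
    return(function(pos) data.frame(gene = NA_integer_, cds_pos = NA_integer_)[rep(1, length(pos)), ])
  ex <- do.call(rbind, lapply(seq_along(genes), function(i)
    data.frame(start = genes[[i]]$cds$start, end = genes[[i]]$cds$end, gene = i)))
  ex <- ex[order(ex$start), ]
  maps <- lapply(genes, function(g) {
    p <- sort(unlist(Map(seq.int, g$cds$start, g$cds$end)))
    if (identical(g$strand, "-")) p <- rev(p)
    p
  })
  function(pos) {
    idx <- findInterval(pos, ex$start)
    gene <- ifelse(idx >= 1 & pos <= ex$end[pmax(idx, 1)], ex$gene[pmax(idx, 1)], NA_integer_)
    cds_pos <- rep(NA_integer_, length(pos))
    hit <- which(!is.na(gene))
    for (i in hit) cds_pos[i] <- match(pos[i], maps[[gene[i]]])
    data.frame(gene = gene, cds_pos = cds_pos)
  }
}

# alt alleles (and coding effects) for sites. A site landing in a CDS is
# repositioned within its gene: the effect class is chosen first with
# nonsynonymous opportunities weighted by omega, then a (position, allele)
# change of that class is drawn uniformly - so the realized nonsynonymous
# fraction among coding variants is omega*N / (omega*N + S) by construction
.draw_alleles <- function(pos, genes, resolver, omega) {
  res <- resolver(pos)
  ref <- rep("A", length(pos))
  alt <- character(length(pos))
  effect <- rep("noncoding", length(pos))
  plain <- which(is.na(res$gene))
  if (length(plain) > 0)
    alt[plain] <- sample(c("C", "G", "T"), length(plain), replace = TRUE)
  for (i in which(!is.na(res$gene))) {
    g <- genes[[res$gene[i]]]
    n_n <- nrow(g$nonsyn_changes); n_s <- nrow(g$syn_changes)
    f <- omega * n_n / (omega * n_n + n_s)
    pick_nonsyn <- (n_s == 0) || (n_n > 0 && stats::runif(1) < f)
    tab <- if (pick_nonsyn) g$nonsyn_changes else g$syn_changes
    j <- sample.int(nrow(tab), 1)
    cds_pos <- tab$cds_pos[j]
    b <- substr(g$cds_seq, cds_pos, cds_pos)
    alt_cds <- tab$alt[j]
    if (identical(g$strand, "-")) {
      ref[i] <- complement_base(b)
      alt[i] <- complement_base(alt_cds)
    } else {
      ref[i] <- b
      alt[i] <- alt_cds
    }
    pos[i] <- g$cds_map[cds_pos]
    effect[i] <- if (pick_nonsyn) "nonsynonymous" else "synonymous"
  }
  data.frame(pos = pos, ref = ref, alt = alt, effect = effect,
             stringsAsFactors = FALSE)
}

# genotype codes for a polymorphic site: k derived copies among 2n slots,
# resampled if the realized configuration collides with a diagnostic X/Y/
# shared pattern (so truth labels stay exact)
.poly_genotypes <- function(k, n_ind, male_idx, female_idx, max_try = 20) {
  for (try in seq_len(max_try)) {
    slots <- sample.int(2 * n_ind, k)
    g <- tabulate((slots + 1) %/% 2, nbins = n_ind)
    males <- g[male_idx]; females <- g[female_idx]
    coll <- (length(males) > 0 && all(males == 1L) &&
               length(unique(females)) == 1 && females[1] %in% c(0L, 2L)) ||
      (length(unique(females)) == 1 && females[1] == 2L)
    if (!coll) return(as.integer(g))
  }
  NULL
}

.sfs_draw <- function(n_sites, n_chrom_copies) {
  i <- seq_len(n_chrom_copies - 1)
  sample(i, n_sites, replace = TRUE, prob = 1 / i)
}

#' Simulate a full resequencing dataset with known truth
#'
#' Generates reference sequences, biallelic diploid genotypes, binned
#' per-sample coverage, coding gene models, an expression matrix and truth
#' tables under a two-species neo-sex-chromosome design:
#' * neo-sex chromosome: X-Y divergent sites (all focal males heterozygous)
#'   at per-bp probability `p_max * exp(-d / scale)` at distance d from the
#'   fusion end, split between X-specific and Y-specific lineages; focal
#'   polymorphism reduced by `focal_poly_factor`.
#' * ancestral sex chromosome: X-Y heterozygous sites in all males of both
#'   species outside the deleted span; male depth multiplied by
#'   `male_depth_factor` over the deleted span, where male heterozygous
#'   polymorphisms are re-called homozygous (hemizygosity as mapped data
#'   would present it).
#' * all chromosomes: fixed inter-species differences, within-species
#'   polymorphism with a 1/i-shaped allele-frequency spectrum, outgroup
#'   divergence. Variants inside CDS have alt alleles drawn with
#'   nonsynonymous changes weighted by the configured dN/dS.
#'
#' Identical seeds give identical datasets.
#'
#' @param cfg [sim_config()].
#' @return list of class `sim_dataset`: `sample_sheet`, `gm`
#'   ([genotype_matrix()]), `coverage` ([coverage_track()]), `genes`,
#'   `reference` (named list of chromosome sequences), `expression`,
#'   `truth` (per-site data.frame with `truth`, `expected_xy`,
#'   `expected_fixed`, `expected_poly_focal`, `expected_poly_sister`,
#'   `effect`), `chrom_lengths`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  sheet <- sim_sample_sheet(cfg)
  ids <- sheet$sample_id
  n_smp <- length(ids)
  is_male <- sheet$sex == "male"
  focal <- sheet$species == "focal"
  sister <- sheet$species == "sister"
  outg <- sheet$species == "outgroup"
  fm <- which(focal & is_male); ff <- which(focal & !is_male)
  sm <- which(sister & is_male); sf <- which(sister & !is_male)

  chroms <- c(sprintf("chrA%02d", seq_len(cfg$n_autosomes)), "chrAncSex", "chrNeoSex")
  chrom_lengths <- stats::setNames(
    c(rep(cfg$autosome_length, cfg$n_autosomes), cfg$anc_sex$length, cfg$neo_sex$length),
    chroms)

  genes <- list()
  site_chunks <- list()
  geno_chunks <- list()
  truth_chunks <- list()

  del <- cfg$anc_sex$deleted_span
  pmax_ <- cfg$neo_sex$p_max
  scale_ <- cfg$neo_sex$decay_scale
  decay_p <- function(d) {
    if (cfg$neo_sex$decay == "exponential") pmax_ * exp(-d / scale_)
    else pmax_ / (1 + exp((d - scale_) / (scale_ / 4)))
  }

  for (chr in chroms) {
    len <- chrom_lengths[[chr]]
    g_chr <- .sim_genes_for_chrom(chr, len, cfg)
    genes <- c(genes, g_chr)
    resolver <- .cds_resolver(g_chr)
    used <- integer(0)
    add_sites <- function(pos, geno, truth, expected_xy, omega) {
      if (length(pos) == 0) return(invisible(NULL))
      al <- .draw_alleles(pos, g_chr, resolver, omega)
      pos <- al$pos # coding sites may have been repositioned within a gene
      keep <- !(pos %in% used) & !duplicated(pos)
      if (!any(keep)) return(invisible(NULL))
      used <<- c(used, pos[keep])
      site_chunks[[length(site_chunks) + 1]] <<- data.frame(
        chrom = chr, pos = pos[keep], ref = al$ref[keep], alt = al$alt[keep],
        stringsAsFactors = FALSE)
      geno_chunks[[length(geno_chunks) + 1]] <<- geno[keep, , drop = FALSE]
      truth_chunks[[length(truth_chunks) + 1]] <<- data.frame(
        truth = truth[keep], expected_xy = expected_xy[keep], effect = al$effect[keep],
        stringsAsFactors = FALSE)
      invisible(NULL)
    }
    const_geno <- function(n, pattern) {
      matrix(rep(pattern, each = n), nrow = n)
    }

    if (chr == "chrNeoSex") {
      # X-Y divergent sites with the fusion-distance gradient
      bin <- 1000
      starts <- seq(1, len, by = bin)
      d <- abs(pmin(starts + bin - 1, len) / 2 + starts / 2 - cfg$neo_sex$fusion_end)
      counts <- stats::rbinom(length(starts), size = bin, prob = decay_p(d))
      pos <- unlist(lapply(which(counts > 0), function(i)
        starts[i] + sample.int(bin, counts[i]) - 1))
      pos <- unique(pos[pos <= len])
      if (length(pos) > 0) {
        on_x <- stats::runif(length(pos)) < cfg$neo_sex$x_fraction
        pat_x <- integer(n_smp); pat_x[fm] <- 1L; pat_x[ff] <- 2L
        pat_y <- integer(n_smp); pat_y[fm] <- 1L
        gx <- const_geno(sum(on_x), pat_x)
        gy <- const_geno(sum(!on_x), pat_y)
        add_sites(pos[on_x], gx, rep("X_specific", sum(on_x)),
                  rep("X_specific", sum(on_x)), cfg$neo_sex$coding_omega[["X_specific"]])
        add_sites(pos[!on_x], gy, rep("Y_specific", sum(!on_x)),
                  rep("Y_specific", sum(!on_x)), cfg$neo_sex$coding_omega[["Y_specific"]])
      }
    }

    if (chr == "chrAncSex" && cfg$anc_sex$xy_het_rate > 0) {
      # ancestral X-Y divergence: all males of both species heterozygous,
      # only outside the deleted span (the Y allele is gone inside it)
      n <- stats::rbinom(1, len, cfg$anc_sex$xy_het_rate)
      pos <- sample.int(len, n)
      pos <- pos[pos < del[1] | pos > del[2]]
      if (length(pos) > 0) {
        pat <- integer(n_smp); pat[c(fm, sm)] <- 1L
        add_sites(pos, const_geno(length(pos), pat),
                  rep("anc_xy", length(pos)), rep("Y_specific", length(pos)),
                  cfg$species$background_omega)
      }
    }

    # fixed inter-species differences
    n_fix <- stats::rbinom(1, len, cfg$species$fixed_diff_rate)
    if (n_fix > 0) {
      pos <- sample.int(len, n_fix)
      derived_focal <- stats::runif(n_fix) < 0.5
      pat_f <- integer(n_smp); pat_f[focal] <- 2L
      pat_s <- integer(n_smp); pat_s[sister] <- 2L
      lab <- if (chr == "chrNeoSex") "shared" else "fixed_diff"
      add_sites(pos[derived_focal], const_geno(sum(derived_focal), pat_f),
                rep(lab, sum(derived_focal)), rep("shared", sum(derived_focal)),
                cfg$species$background_omega)
      add_sites(pos[!derived_focal], const_geno(sum(!derived_focal), pat_s),
                rep(lab, sum(!derived_focal)), rep("shared", sum(!derived_focal)),
                cfg$species$background_omega)
    }

    # outgroup divergence
    n_og <- stats::rbinom(1, len, cfg$species$outgroup_divergence_rate)
    if (n_og > 0) {
      pos <- sample.int(len, n_og)
      pat <- integer(n_smp); pat[outg] <- 2L
      add_sites(pos, const_geno(n_og, pat),
                rep("outgroup_divergent", n_og), rep("unclassified", n_og),
                cfg$species$background_omega)
    }

    # within-species polymorphism
    for (sp in c("focal", "sister")) {
      rate <- cfg$species$polymorphism_rate
      if (sp == "focal" && chr == "chrNeoSex") rate <- rate * cfg$neo_sex$focal_poly_factor
      sp_idx <- which(sheet$species == sp)
      male_loc <- which(sheet$sex[sp_idx] == "male")
      female_loc <- which(sheet$sex[sp_idx] == "female")
      n_p <- stats::rbinom(1, len, rate)
      if (n_p == 0) next
      pos <- sample.int(len, n_p)
      ks <- .sfs_draw(n_p, 2 * length(sp_idx))
      geno <- matrix(0L, n_p, n_smp)
      ok <- logical(n_p)
      for (i in seq_len(n_p)) {
        gg <- .poly_genotypes(ks[i], length(sp_idx), male_loc, female_loc)
        if (is.null(gg)) next
        geno[i, sp_idx] <- gg
        ok[i] <- TRUE
      }
      # hemizygous re-call: male het inside the ancestral deleted span
      if (chr == "chrAncSex") {
        males_all <- which(is_male)
        in_del <- pos >= del[1] & pos <= del[2]
        for (j in males_all) {
          flip <- in_del & geno[, j] == 1L
          if (any(flip)) geno[flip, j] <- 2L * (stats::runif(sum(flip)) < 0.5)
        }
      }
      add_sites(pos[ok], geno[ok, , drop = FALSE],
                rep(paste0("polymorphic_", sp), sum(ok)),
                rep("unclassified", sum(ok)), cfg$species$background_omega)
    }
  }

  if (length(site_chunks) == 0) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE)
    geno <- matrix(integer(0), 0, n_smp)
    truth <- data.frame(truth = character(0), expected_xy = character(0),
                        effect = character(0), stringsAsFactors = FALSE)
  } else {
    sites <- do.call(rbind, site_chunks)
    geno <- do.call(rbind, geno_chunks)
    truth <- do.call(rbind, truth_chunks)
  }
  colnames(geno) <- ids
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(sites) <- rownames(truth) <- NULL

  # expected species-site classes from the realized female genotypes
  gf <- geno[, ids[ff], drop = FALSE]
  gs <- geno[, ids[sf], drop = FALSE]
  hom_same <- function(m) (rowSums(m == m[, 1]) == ncol(m)) & (m[, 1] %in% c(0L, 2L))
  poly_rows <- function(m) {
    mx <- mn <- m[, 1]
    for (j in seq_len(ncol(m))) { mx <- pmax(mx, m[, j]); mn <- pmin(mn, m[, j]) }
    rowSums(m == 1L) > 0 | mx != mn
  }
  if (ncol(gf) > 0 && ncol(gs) > 0) {
    truth$expected_fixed <- hom_same(gf) & hom_same(gs) & gf[, 1] != gs[, 1]
    truth$expected_poly_focal <- poly_rows(gf) & !truth$expected_fixed
    truth$expected_poly_sister <- poly_rows(gs) & !truth$expected_fixed
  } else {
    truth$expected_fixed <- truth$expected_poly_focal <-
      truth$expected_poly_sister <- rep(FALSE, nrow(truth))
  }

  # per-sample mean depth and per-site DP
  mu <- stats::setNames(cfg$depth$mean * stats::runif(n_smp, 0.8, 1.2), ids)
  lam <- matrix(rep(mu, each = nrow(sites)), nrow = nrow(sites), ncol = n_smp)
  in_del_site <- sites$chrom == "chrAncSex" & sites$pos >= del[1] & sites$pos <= del[2]
  lam[in_del_site, is_male] <- lam[in_del_site, is_male] * cfg$anc_sex$male_depth_factor
  dp <- matrix(stats::rpois(length(lam), lam), nrow = nrow(sites), ncol = n_smp,
               dimnames = list(NULL, ids))

  gm <- genotype_matrix(sites, geno, dp)

  # binned coverage with shared repeat-masked (zero) bins
  bs <- cfg$depth$bin_size
  zero_bins <- lapply(chroms, function(chr) {
    nb <- ceiling(chrom_lengths[[chr]] / bs)
    which(stats::runif(nb) < cfg$depth$zero_bin_rate)
  })
  names(zero_bins) <- chroms
  depth_list <- list()
  for (j in seq_len(n_smp)) {
    s <- ids[j]
    per_chrom <- list()
    for (chr in chroms) {
      nb <- ceiling(chrom_lengths[[chr]] / bs)
      v <- stats::rgamma(nb, shape = cfg$depth$dispersion,
                         rate = cfg$depth$dispersion / mu[[s]])
      if (chr == "chrAncSex" && is_male[j]) {
        starts <- (seq_len(nb) - 1) * bs + 1
        ends <- pmin(starts + bs - 1, chrom_lengths[[chr]])
        ov <- pmax(0, pmin(ends, del[2]) - pmax(starts, del[1]) + 1) / (ends - starts + 1)
        v <- v * (1 - ov * (1 - cfg$anc_sex$male_depth_factor))
      }
      v[zero_bins[[chr]]] <- 0
      per_chrom[[chr]] <- v
    }
    depth_list[[s]] <- per_chrom
  }
  lib <- vapply(ids, function(s) {
    round(sum(vapply(chroms, function(chr) {
      w <- bin_widths(chrom_lengths[[chr]], bs)
      sum(depth_list[[s]][[chr]] * w)
    }, numeric(1))) / 100)
  }, numeric(1))
  cov <- coverage_track(depth_list, bs, chrom_lengths, lib)

  expr <- .sim_expression_integrated(cfg, genes, decay_p)

  structure(list(sample_sheet = sheet, gm = gm, coverage = cov, genes = genes,
                 expression = expr, truth = truth,
                 chrom_lengths = chrom_lengths,
                 deleted_span = del, cfg = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d samples, %d chromosomes, %d variant sites, %d genes\n",
              nrow(x$sample_sheet), length(x$chrom_lengths), nrow(x$gm$sites),
              length(x$genes)))
  print(table(x$truth$truth))
  invisible(x)
}

# brain/gonad expression for the focal species over the dataset's genes;
# sex effects of neo-sex genes are coupled to their expected upstream X-Y
# heterozygosity so the cis-correlation analysis has signal
.sim_expression_integrated <- function(cfg, genes, decay_p) {
  ex <- cfg$expression
  n_g <- length(genes)
  if (n_g == 0) return(NULL)
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  gene_chrom <- vapply(genes, `[[`, character(1), "chrom")
  tss <- vapply(genes, function(g)
    if (identical(g$strand, "-")) max(g$cds$end) else min(g$cds$start), numeric(1))
  arrays <- expand.grid(rep = seq_len(ex$n_reps), sex = c("male", "female"),
                        tissue = c("brain", "gonad"), stringsAsFactors = FALSE)
  arrays$array_id <- sprintf("%s_%s_%d", arrays$tissue, arrays$sex, arrays$rep)
  on_neo <- gene_chrom == "chrNeoSex"
  frac <- ifelse(on_neo, ex$biased_fraction_neo, ex$biased_fraction_autosome)
  biased <- stats::runif(n_g) < frac
  bias_dir <- sample(c(-1, 1), n_g, replace = TRUE)
  up_het <- ifelse(on_neo,
                   decay_p(abs(tss - cfg$neo_sex$fusion_end)) * 10000, 0)
  effect <- ifelse(biased, bias_dir * ex$effect_log2, 0) +
    ex$cis_coupling * up_het
  base <- stats::rlnorm(n_g, meanlog = log(100), sdlog = 1)
  sig <- matrix(0, n_g, nrow(arrays), dimnames = list(gene_ids, arrays$array_id))
  for (a in seq_len(nrow(arrays))) {
    shift <- if (arrays$sex[a] == "male") effect / 2 else -effect / 2
    sig[, a] <- base * 2^(shift + stats::rnorm(n_g, 0, ex$sd_log2))
  }
  list(signal = sig, arrays = arrays,
       gene_map = data.frame(gene_id = gene_ids, chrom = gene_chrom, tss = tss,
                             strand = vapply(genes, `[[`, character(1), "strand"),
                             stringsAsFactors = FALSE),
       truth = data.frame(gene_id = gene_ids, biased = biased,
                          effect_log2 = effect, stringsAsFactors = FALSE))
}

#' Simulate three aligned coding sequences with branch-specific dN/dS
#'
#' From an ancestral ORF, places substitutions independently on the focal,
#' sister and outgroup-lineage branches of the tree ((focal, sister),
#' outgroup). Per branch, synonymous and nonsynonymous substitution counts
#' are drawn as Poisson with means S*ks and N*ks*omega (S, N = ancestral
#' NG86 site counts) and placed at uniformly chosen eligible positions of
#' the required class; stop codons are never created and the start codon is
#' left intact.
#'
#' @param n_codons ancestral ORF length in codons (ignored when `cds`
#'   given).
#' @param branch_omegas named numeric: `focal`, `sister`, `ancestral`.
#' @param ks expected synonymous divergence per branch (substitutions per
#'   synonymous site).
#' @param cds optional ancestral CDS (valid ORF).
#' @param seed optional seed.
#' @return list with `focal`, `sister`, `outgroup`, `ancestral` CDS strings
#'   and `truth` (per-branch placed counts, `N`, `S`).
#' @export
simulate_coding_divergence <- function(n_codons = 300,
                                       branch_omegas = c(focal = 0.5, sister = 0.1,
                                                         ancestral = 0.1),
                                       ks = 0.05, cds = NULL, seed = NULL) {
  with_local_seed(seed, {
    anc <- cds %||% random_orf(n_codons)
    syn <- codon_syn_sites()
    cods <- split_codons(anc)
    S <- sum(syn[cods]); N <- 3 * length(cods) - S
    place <- function(seq, n_syn, n_nonsyn) {
      gc <- Biostrings::GENETIC_CODE
      total <- n_syn + n_nonsyn
      if (total > nchar(seq) - 3) stop("requested substitution count exceeds sites")
      want <- c(rep("synonymous", n_syn), rep("nonsynonymous", n_nonsyn))
      want <- sample(want)
      for (cls in want) {
        repeat {
          p <- sample(4:nchar(seq), 1) # never touch the start codon
          cod_start <- 3 * ((p - 1) %/% 3) + 1
          codon <- substring(seq, cod_start, cod_start + 2)
          off <- p - cod_start + 1
          b <- sample(setdiff(.BASES, substr(codon, off, off)), 1)
          nc <- codon
          substr(nc, off, off) <- b
          if (gc[nc] == "*") next
          eff <- if (gc[nc] == gc[codon]) "synonymous" else "nonsynonymous"
          if (eff == cls) {
            substr(seq, p, p) <- b
            break
          }
        }
      }
      seq
    }
    counts <- lapply(c(focal = "focal", sister = "sister", ancestral = "ancestral"),
                     function(br) {
                       om <- branch_omegas[[br]]
                       c(syn = stats::rpois(1, S * ks),
                         nonsyn = stats::rpois(1, N * ks * om))
                     })
    focal <- place(anc, counts$focal["syn"], counts$focal["nonsyn"])
    sister <- place(anc, counts$sister["syn"], counts$sister["nonsyn"])
    outgroup <- place(anc, counts$ancestral["syn"], counts$ancestral["nonsyn"])
    list(focal = focal, sister = sister, outgroup = outgroup, ancestral = anc,
         truth = list(counts = counts, N = N, S = S,
                      branch_omegas = branch_omegas, ks = ks))
  })
}

#' Simulate per-gene expression for chromosome-enrichment testing
#'
#' Normalized (log-scale) two-group expression values with a configurable
#' fraction of truly biased genes per chromosome, for power and null
#' calibration of [call_biased_genes()] + [chromosome_enrichment()].
#'
#' @param chroms chromosome names.
#' @param genes_per_chrom genes per chromosome.
#' @param biased_fraction named (or recycled) per-chromosome fraction of
#'   truly biased genes.
#' @param effect between-group mean shift for biased genes (in within-group
#'   SD units times `sd`).
#' @param n_per_group replicates per group.
#' @param sd within-group SD.
#' @param seed optional seed.
#' @return list with `mat` (genes x arrays), `groups` factor, `gene_chrom`,
#'   `truth_biased`.
#' @export
simulate_expression_study <- function(chroms, genes_per_chrom = 300,
                                      biased_fraction = 0.05, effect = 3,
                                      n_per_group = 4, sd = 1, seed = NULL) {
  with_local_seed(seed, {
    if (length(biased_fraction) == 1)
      biased_fraction <- stats::setNames(rep(biased_fraction, length(chroms)), chroms)
    n_g <- genes_per_chrom * length(chroms)
    gene_chrom <- rep(chroms, each = genes_per_chrom)
    truth <- stats::runif(n_g) < biased_fraction[gene_chrom]
    groups <- factor(rep(c("g1", "g2"), each = n_per_group))
    shift <- ifelse(truth, effect * sd, 0)
    mat <- matrix(stats::rnorm(n_g * 2 * n_per_group, sd = sd), n_g)
    mat[, groups == "g2"] <- mat[, groups == "g2"] + shift
    rownames(mat) <- sprintf("gene%05d", seq_len(n_g))
    list(mat = mat, groups = groups,
         gene_chrom = stats::setNames(gene_chrom, rownames(mat)),
         truth_biased = stats::setNames(truth, rownames(mat)))
  })
}

#' Write a simulated dataset to standard files
#'
#' Emits reference FASTA, VCF, per-sample bedGraph coverage, GFF3 gene
#' models, expression and truth TSVs, and the sample sheet, in the formats
#' the package's readers consume.
#'
#' @param ds [simulate_dataset()] result.
#' @param dir output directory.
#' @param reference write the (large) reference FASTA; the sequence is
#'   reconstructed from gene models with filler elsewhere.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, reference = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ds$sample_sheet, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotypes(ds$gm, file.path(dir, "genotypes.vcf"))
  write_coverage(ds$coverage, file.path(dir, "coverage"))
  write_gene_models(ds$genes, file.path(dir, "genes.gff3"))
  if (reference) {
    seqs <- build_reference(ds)
    con <- file(file.path(dir, "reference.fa"), "w")
    for (chr in names(seqs)) {
      writeLines(paste0(">", chr), con)
      s <- seqs[[chr]]
      starts <- seq(1, nchar(s), by = 70)
      writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
    }
    close(con)
  }
  if (!is.null(ds$expression)) {
    sig <- ds$expression$signal
    utils::write.table(data.frame(gene_id = rownames(sig), sig, check.names = FALSE),
                       file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ds$expression$gene_map, file.path(dir, "gene_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  utils::write.table(cbind(ds$gm$sites, ds$truth), file.path(dir, "truth", "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = "chrAncSex", start = ds$deleted_span[1], end = ds$deleted_span[2]),
    file.path(dir, "truth", "deleted_region.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Reconstruct reference chromosome sequences
#'
#' Gene CDS sequences placed at their genomic coordinates (strand-aware)
#' over filler 'A'; no computed statistic depends on the filler.
#'
#' @param ds [simulate_dataset()] result.
#' @return named list of chromosome sequences.
#' @export
build_reference <- function(ds) {
  out <- list()
  for (chr in names(ds$chrom_lengths)) {
    s <- strrep("A", ds$chrom_lengths[[chr]])
    for (g in ds$genes) {
      if (g$chrom != chr) next
      cds_seq <- g$cds_seq
      if (identical(g$strand, "-")) cds_seq <- revcomp(cds_seq)
      offset <- 0
      for (i in order(g$cds$start)) {
        w <- g$cds$end[i] - g$cds$start[i] + 1
        substr(s, g$cds$start[i], g$cds$end[i]) <-
          substring(cds_seq, offset + 1, offset + w)
        offset <- offset + w
      }
    }
    out[[chr]] <- s
  }
  out
}
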