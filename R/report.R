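#' Run the full neo-sex chromosome analysis pipeline
#'
#' Orchestrates the coverage, divergence, codon-evolution and expression
#' analyses over a dataset (typically a [simulate_dataset()] result, or any
#' list providing the same components) and returns all stage outputs plus a
#' machine-readable run manifest. Stage failures are isolated: an error in
#' one stage is recorded in `errors` and later stages still run.
#'
#' @param ds dataset list: `sample_sheet`, `gm`, `coverage`, `genes`,
#'   `chrom_lengths`, optionally `expression`, `cfg`.
#' @param out_dir optional output directory for tables (TSV/BED/JSON).
#' @param candidates candidate sex chromosomes.
#' @param fusion_end fusion-end coordinate on the neo-sex chromosome.
#' @param alpha significance level used for outlier screens.
#' @param seed seed for the stochastic steps (virtual haplotypes, consensus
#'   sequences).
#' @return object of class `neosex_report`.
#' @export
run_pipeline <- function(ds, out_dir = NULL,
                         candidates = c("chrAncSex", "chrNeoSex"),
                         fusion_end = NULL, alpha = 0.01, seed = 1L) {
  sheet <- ds$sample_sheet
  roles <- sample_roles(sheet, "focal", "sister", "outgroup")
  autosomes <- setdiff(names(ds$chrom_lengths), candidates)
  fusion_end <- fusion_end %||% (if (!is.null(ds$cfg)) ds$cfg$neo_sex$fusion_end else 1)
  neo <- "chrNeoSex"; anc <- "chrAncSex"
  res <- list(errors = list(), counts = list())
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    res[[name]] <<- out
    invisible(out)
  }

  # --- coverage: degeneration screen and sex-difference windows
  stage("coverage", {
    norm <- normalize_coverage(ds$coverage)
    cm <- chromosome_mean_coverage(norm)
    deg <- detect_degeneration(cm, sheet, candidates, autosomes, alpha = alpha)
    m1 <- roles$focal_males[1]; f1 <- roles$focal_females[1]
    sw <- sex_coverage_windows(norm, m1, f1)
    deficit <- locate_coverage_deficit(sw[sw$chrom == anc, ])
    list(chrom_means = cm, degeneration = deg,
         sex_windows = sw[sw$chrom %in% candidates, ], deficit_anc = deficit)
  })

  # --- masks from the raw coverage of the role samples
  role_samples <- c(roles$focal_males, roles$focal_females, roles$other_females)
  mask_strict <- build_site_mask(ds$coverage, role_samples,
                                 mask_preset("strict")[1], mask_preset("strict")[2])
  mask_loose <- build_site_mask(ds$coverage, role_samples,
                                mask_preset("loose")[1], mask_preset("loose")[2])
  res$masks <- list(strict = mask_strict, loose = mask_loose)

  # --- heterozygosity: chromosome aggregates, windows, fusion gradient
  stage("heterozygosity", {
    m1 <- roles$focal_males[1]; f1 <- roles$focal_females[1]
    sm1 <- roles$other_males[1]
    chrom_het <- list(focal_male = chromosome_het_proportion(ds$gm, m1, mask_strict),
                      focal_female = chromosome_het_proportion(ds$gm, f1, mask_strict))
    if (length(sm1) > 0 && !is.na(sm1))
      chrom_het$other_male <- chromosome_het_proportion(ds$gm, sm1, mask_strict)
    het_outliers <- lapply(chrom_het, function(ch) {
      do.call(rbind, lapply(candidates, function(cand) {
        vals <- c(ch$value[match(autosomes, ch$chrom)], ch$value[match(cand, ch$chrom)])
        g <- grubbs_test(vals, length(vals))
        data.frame(chrom = cand, value = ch$value[match(cand, ch$chrom)],
                   G = g$statistic, p = g$p.value, direction = g$direction,
                   significant = g$p.value < alpha, stringsAsFactors = FALSE)
      }))
    })
    hw_m <- het_windows(ds$gm, m1, mask_strict)
    hw_f <- het_windows(ds$gm, f1, mask_strict)
    ok <- mask_sites(mask_strict, ds$gm$sites$chrom, ds$gm$sites$pos)
    het_pos <- ds$gm$sites$pos[ds$gm$sites$chrom == neo & ok &
                                 !is.na(ds$gm$geno[, m1]) & ds$gm$geno[, m1] == 1L]
    grad <- fusion_gradient(neo, het_pos, mask_strict, fusion_end)
    list(chrom_het = chrom_het, het_outliers = het_outliers,
         windows_male = hw_m[hw_m$chrom %in% candidates, ],
         windows_female = hw_f[hw_f$chrom %in% candidates, ],
         gradient = grad)
  })

  # --- X/Y SNP classification and coding effects
  stage("xy_snps", {
    cls <- classify_xy_snps(ds$gm, roles, mask_strict)
    classified <- which(cls != "unclassified")
    eff <- rep(NA_character_, length(cls))
    if (length(classified) > 0)
      eff[classified] <- annotate_snp_effect(ds$gm$sites[classified, , drop = FALSE],
                                             ds$genes)
    nsf <- nonsyn_fraction_by_category(as.character(cls[classified]), eff[classified])
    xw <- site_class_windows(ds$gm, cls == "X_specific", mask_strict)
    yw <- site_class_windows(ds$gm, cls == "Y_specific", mask_strict)
    list(category = cls, counts = attr(cls, "counts"), effects = eff,
         nonsyn_fraction = nsf,
         windows_x = xw[xw$chrom == neo, ], windows_y = yw[yw$chrom == neo, ])
  })

  # --- fixed differences and polymorphism between/within species
  stage("species_sites", {
    sc <- classify_species_sites(ds$gm, roles$focal_females, roles$other_females,
                                 mask_loose)
    per_chrom <- function(flag) {
      vapply(names(ds$chrom_lengths), function(chr) {
        den <- usable_bp(mask_loose, chr, 1, mask_loose$chrom_lengths[[chr]])
        if (den > 0) sum(flag & ds$gm$sites$chrom == chr) / den else NA_real_
      }, numeric(1))
    }
    props <- list(fixed = per_chrom(sc$fixed_diff),
                  poly_focal = per_chrom(sc$polymorphic_a),
                  poly_sister = per_chrom(sc$polymorphic_b))
    outliers <- lapply(props, function(v) {
      do.call(rbind, lapply(candidates, function(cand) {
        g <- grubbs_test(c(v[autosomes], v[cand]), length(autosomes) + 1)
        data.frame(chrom = cand, value = v[[cand]], G = g$statistic, p = g$p.value,
                   direction = g$direction, significant = g$p.value < alpha,
                   stringsAsFactors = FALSE)
      }))
    })
    wf <- site_class_windows(ds$gm, sc$fixed_diff, mask_loose, relative_to = autosomes)
    wp <- site_class_windows(ds$gm, sc$polymorphic_a, mask_loose, relative_to = autosomes)
    list(site_class = sc, proportions = props, outliers = outliers,
         windows_fixed = wf[wf$chrom == neo, ], windows_poly = wp[wp$chrom == neo, ])
  })

  # --- Ka/Ks between virtual X/Y haplotypes; lineage-specific two-ratio
  stage("kaks", {
    m1 <- roles$focal_males[1]
    rows <- lapply(seq_along(ds$genes), function(i) {
      g <- ds$genes[[i]]
      hp <- build_virtual_haplotypes(ds$gm, m1, g, seed = seed + i)
      if (is.null(hp)) return(NULL)
      kk <- ng86_kaks(hp$hap1, hp$hap2)
      data.frame(gene_id = g$gene_id, chrom = g$chrom, Ka = kk$Ka, Ks = kk$Ks,
                 ka_ks = kk$ka_ks, Nd = kk$Nd, Sd = kk$Sd, n_het = hp$n_het,
                 stringsAsFactors = FALSE)
    })
    xy <- do.call(rbind, Filter(Negate(is.null), rows))
    lin <- lapply(seq_along(ds$genes), function(i) {
      g <- ds$genes[[i]]
      fc <- consensus_haploid(ds$gm, roles$focal_females[1], g, seed = seed + i)
      sc_ <- consensus_haploid(ds$gm, roles$other_females[1], g, seed = seed + 1000 + i)
      oc <- consensus_haploid(ds$gm, roles$outgroup[1], g, seed = seed + 2000 + i)
      if (is.null(fc) || is.null(sc_) || is.null(oc)) return(NULL)
      bo <- branch_specific_omega(fc, sc_, oc)
      data.frame(gene_id = g$gene_id, chrom = g$chrom, omega1 = bo$omega1,
                 omega0 = bo$omega0, Nd1 = bo$Nd1, Sd1 = bo$Sd1,
                 Nd0 = bo$Nd0, Sd0 = bo$Sd0, stringsAsFactors = FALSE)
    })
    lineage <- do.call(rbind, Filter(Negate(is.null), lin))
    mw_xy <- {
      a <- xy$ka_ks[xy$chrom == neo & !is.na(xy$ka_ks)]
      b <- xy$ka_ks[xy$chrom %in% autosomes & !is.na(xy$ka_ks)]
      if (length(a) >= 2 && length(b) >= 2) mann_whitney_u(a, b) else NULL
    }
    list(xy = xy, lineage = lineage, mw_neo_vs_autosomes = mw_xy,
         method = "NG86-two-ratio")
  })

  # --- expression: sex bias, enrichment, cis-heterozygosity correlation
  if (!is.null(ds$expression)) stage("expression", {
    ex <- ds$expression
    brain <- ex$arrays$tissue == "brain"
    norm <- normalize_expression(ex$signal[, brain, drop = FALSE])
    calls <- call_biased_genes(norm$mat, ex$arrays$sex[brain], alpha = 0.01)
    flags <- stats::setNames(calls$flagged, calls$gene)
    gene_chrom <- stats::setNames(ex$gene_map$chrom, ex$gene_map$gene_id)[names(flags)]
    enr <- tryCatch(
      suppressWarnings(chromosome_enrichment(flags, gene_chrom, candidates,
                                             autosomes, min_genes = 10)),
      error = function(e) NULL)
    effect <- stats::setNames(calls$effect, calls$gene)
    cis <- cis_het_correlation(effect, ds$gm, roles$focal_males[1],
                               ex$gene_map, neo)
    list(bias_calls = calls, enrichment = enr, cis_correlation = cis,
         n_excluded_probes = length(norm$excluded_probes))
  })

  # --- manifest
  cfg_str <- paste(deparse(ds$cfg), collapse = "")
  res$manifest <- list(
    package = "neosexscan",
    version = as.character(utils::packageVersion("neosexscan")),
    config_hash = string_hash(cfg_str),
    seed = seed,
    n_samples = nrow(sheet),
    n_sites = nrow(ds$gm$sites),
    n_genes = length(ds$genes),
    stage_counts = list(
      sites_classified = if (!is.null(res$xy_snps)) as.list(res$xy_snps$counts) else NULL,
      genes_kaks = if (!is.null(res$kaks)) nrow(res$kaks$xy) else NULL,
      stages_failed = names(res$errors)))
  class(res) <- "neosex_report"
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' @export
print.neosex_report <- function(x, ...) {
  cat("neosexscan pipeline report\n")
  if (!is.null(x$coverage)) {
    cat("\nCoverage degeneration screen:\n")
    print(x$coverage$degeneration$summary, row.names = FALSE)
  }
  if (!is.null(x$heterozygosity)) {
    cat("\nHeterozygosity outliers (focal male):\n")
    print(x$heterozygosity$het_outliers$focal_male, row.names = FALSE)
    cat(sprintf("\nFusion gradient: beta = %.3g (SE %.2g, p = %.3g)\n",
                x$heterozygosity$gradient$beta, x$heterozygosity$gradient$se_beta,
                x$heterozygosity$gradient$p_beta))
  }
  if (!is.null(x$xy_snps)) {
    cat("\nX/Y SNP categories:\n")
    print(x$xy_snps$counts)
  }
  if (length(x$errors) > 0)
    cat("\nFailed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline report tables
#'
#' Emits the report's tables as TSV/BED/JSON under `dir`. Re-running the
#' pipeline with the same config and seed reproduces identical files.
#'
#' @param res `neosex_report`.
#' @param dir output directory.
#' @export
write_report <- function(res, dir) {
  op <- options(scipen = 15)
  on.exit(options(op))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(res$coverage)) {
    wt(res$coverage$chrom_means, "chrom_means.tsv")
    wt(res$coverage$degeneration$per_sample, "degeneration_per_sample.tsv")
    wt(res$coverage$degeneration$summary, "degeneration_summary.tsv")
    write_windows(res$coverage$sex_windows, file.path(dir, "sex_coverage_windows.bed"))
  }
  if (!is.null(res$heterozygosity)) {
    wt(res$heterozygosity$chrom_het$focal_male, "chrom_het_focal_male.tsv")
    write_windows(res$heterozygosity$windows_male, file.path(dir, "het_windows_male.bed"))
    write_windows(res$heterozygosity$windows_female, file.path(dir, "het_windows_female.bed"))
    g <- res$heterozygosity$gradient
    jsonlite::write_json(list(beta = g$beta, se = g$se_beta, p = g$p_beta,
                              intercept = g$intercept, separated = g$separated,
                              n_bins = g$n_bins_used),
                         file.path(dir, "gradient_fit.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(res$xy_snps)) {
    wt(data.frame(category = names(res$xy_snps$counts),
                  n = as.integer(res$xy_snps$counts)), "xy_snp_counts.tsv")
    wt(res$xy_snps$nonsyn_fraction, "nonsyn_fraction.tsv")
    write_windows(res$xy_snps$windows_x, file.path(dir, "x_specific_windows.bed"))
    write_windows(res$xy_snps$windows_y, file.path(dir, "y_specific_windows.bed"))
  }
  if (!is.null(res$species_sites)) {
    pr <- res$species_sites$proportions
    wt(data.frame(chrom = names(pr$fixed), fixed = unname(pr$fixed),
                  poly_focal = unname(pr$poly_focal),
                  poly_sister = unname(pr$poly_sister)), "species_site_proportions.tsv")
    write_windows(res$species_sites$windows_fixed, file.path(dir, "fixed_diff_windows.bed"))
    write_windows(res$species_sites$windows_poly, file.path(dir, "poly_focal_windows.bed"))
  }
  if (!is.null(res$kaks)) {
    wt(res$kaks$xy, "kaks_xy.tsv")
    wt(res$kaks$lineage, "lineage_omega.tsv")
  }
  if (!is.null(res$expression)) {
    wt(res$expression$bias_calls, "expression_bias_calls.tsv")
    if (!is.null(res$expression$enrichment))
      wt(res$expression$enrichment$per_candidate, "expression_enrichment.tsv")
    wt(res$expression$cis_correlation, "cis_het_correlation.tsv")
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
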