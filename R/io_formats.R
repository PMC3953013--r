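#' Read a sample sheet
#'
#' Three-column TSV with header `sample_id  species  sex`. Sample ids must
#' be unique and sex must be `male` or `female`.
#'
#' @param path TSV path.
#' @return data.frame with columns `sample_id`, `species`, `sex`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "species", "sex")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(sheet$sex), c("male", "female"))
  if (length(bad) > 0) stop("sex must be 'male' or 'female'; found: ", paste(bad, collapse = ", "))
  sheet[, need]
}

#' Map sheet samples to analysis roles
#'
#' Splits samples into the role groups the stratified SNP rules quantify
#' over, by species label and sex.
#'
#' @param sheet sample sheet data.frame.
#' @param focal species label of the species carrying the neo-sex
#'   chromosome.
#' @param other species label of the sister species.
#' @param outgroup optional outgroup species label.
#' @return list with `focal_males`, `focal_females`, `other_males`,
#'   `other_females`, `outgroup` (character vectors of sample ids).
#' @export
sample_roles <- function(sheet, focal, other, outgroup = NULL) {
  pick <- function(sp, sx) sheet$sample_id[sheet$species == sp & sheet$sex == sx]
  list(focal_males = pick(focal, "male"),
       focal_females = pick(focal, "female"),
       other_males = pick(other, "male"),
       other_females = pick(other, "female"),
       outgroup = if (is.null(outgroup)) character(0)
       else sheet$sample_id[sheet$species == outgroup])
}

#' Construct a genotype matrix container
#'
#' @param sites data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param geno integer matrix (sites x samples): 0 = hom ref, 1 = het,
#'   2 = hom alt, NA = missing.
#' @param depth optional integer matrix of per-site per-sample read depth.
#' @param dropped list of counts of excluded records.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, depth = NULL, dropped = list()) {
  stopifnot(nrow(sites) == nrow(geno))
  sites$pos <- as.integer(sites$pos)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  if (!is.null(depth)) {
    depth <- depth[ord, , drop = FALSE]
    dimnames(depth) <- list(NULL, colnames(geno))
  }
  rownames(sites) <- NULL
  for (chr in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == chr]
    if (anyDuplicated(p)) stop("duplicate positions on ", chr)
  }
  structure(list(sites = sites, geno = geno, depth = depth,
                 samples = colnames(geno), dropped = dropped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNVs x %d samples on %d chromosome(s)\n",
              nrow(x$sites), length(x$samples), length(unique(x$sites$chrom))))
  if (length(x$dropped) > 0 && sum(unlist(x$dropped)) > 0)
    cat("  dropped records:",
        paste(sprintf("%s = %d", names(x$dropped), unlist(x$dropped)), collapse = ", "), "\n")
  invisible(x)
}

.gt_to_code <- function(gt) {
  # "0/0" -> 0, "0/1"/"1/0" -> 1, "1/1" -> 2; anything missing -> NA
  gt <- sub("\\|", "/", gt)
  code <- rep(NA_integer_, length(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  code
}

#' Read diploid genotypes from a VCF
#'
#' Parses a VCF 4.x file with vcfR and retains only biallelic SNV records;
#' indels, multiallelic and symbolic-allele records are dropped and
#' counted. Every sample in the sheet must be present in the VCF header.
#'
#' @param vcf_path VCF path (plain or gzipped).
#' @param sample_sheet sample sheet data.frame.
#' @return [genotype_matrix()] restricted to the sheet's samples, with
#'   per-site depth when the VCF carries a DP FORMAT field.
#' @export
read_genotypes <- function(vcf_path, sample_sheet) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1]
  missing <- setdiff(sample_sheet$sample_id, have)
  if (length(missing) > 0)
    stop("samples in sheet but not in VCF: ", paste(missing, collapse = ", "))
  fix <- vcfR::getFIX(vcf)
  if (nrow(vcf@fix) == 0 || is.null(fix) ) {
    return(genotype_matrix(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0), stringsAsFactors = FALSE),
      matrix(integer(0), 0, nrow(sample_sheet),
             dimnames = list(NULL, sample_sheet$sample_id))))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) stop("malformed VCF record (non-numeric POS) at record ",
                       which(is.na(pos))[1])
  ref <- fix$REF; alt <- fix$ALT
  alt[is.na(alt)] <- ""
  multi <- grepl(",", alt)
  symbolic <- grepl("[<>\\[\\]]", alt)
  snv <- !multi & !symbolic & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  indel <- !multi & !symbolic & !snv & nchar(alt) >= 1
  keep <- which(snv)
  if (length(keep) == 0) {
    gm <- genotype_matrix(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0), stringsAsFactors = FALSE),
      matrix(integer(0), 0, nrow(sample_sheet),
             dimnames = list(NULL, sample_sheet$sample_id)),
      dropped = list(indel = sum(indel), multiallelic = sum(multi),
                     other = sum(symbolic)))
    if (gm$dropped$indel > 0) message(gm$dropped$indel, " indel record(s) excluded")
    return(gm)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  geno <- apply(gt[keep, sample_sheet$sample_id, drop = FALSE], 2, .gt_to_code)
  geno <- matrix(as.integer(geno), nrow = length(keep),
                 dimnames = list(NULL, sample_sheet$sample_id))
  depth <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (length(fmt) > 0 && any(grepl("DP", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    depth <- matrix(as.integer(dp[keep, sample_sheet$sample_id, drop = FALSE]),
                    nrow = length(keep),
                    dimnames = list(NULL, sample_sheet$sample_id))
  }
  gm <- genotype_matrix(
    data.frame(chrom = fix$CHROM[keep], pos = pos[keep],
               ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE),
    geno, depth,
    dropped = list(indel = sum(indel), multiallelic = sum(multi),
                   other = sum(symbolic) + sum(!snv & !indel & !multi & !symbolic)))
  if (gm$dropped$indel > 0)
    message(gm$dropped$indel, " indel record(s) excluded")
  gm
}

.code_to_gt <- function(code) {
  gt <- rep("./.", length(code))
  gt[!is.na(code) & code == 0L] <- "0/0"
  gt[!is.na(code) & code == 1L] <- "0/1"
  gt[!is.na(code) & code == 2L] <- "1/1"
  gt
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 with GT (and DP when present) FORMAT fields.
#' Reading the file back with [read_genotypes()] reproduces the matrix.
#'
#' @param gm [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(gm, path) {
  op <- options(scipen = 15)
  on.exit(options(op), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  n <- nrow(gm$sites)
  if (n > 0) {
    has_dp <- !is.null(gm$depth)
    fmt <- if (has_dp) "GT:DP" else "GT"
    cells <- matrix("", n, length(gm$samples))
    for (j in seq_along(gm$samples)) {
      g <- .code_to_gt(gm$geno[, j])
      cells[, j] <- if (has_dp) paste0(g, ":", ifelse(is.na(gm$depth[, j]), ".", gm$depth[, j])) else g
    }
    lines <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                   ".", "PASS", ".", fmt,
                   apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Construct a coverage track
#'
#' Per-sample read depth in fixed-width bins (bin_size = 1 gives
#' per-position depth). Zero depth marks uncovered or repeat-masked
#' positions.
#'
#' @param depth named list: sample -> named list: chrom -> numeric vector of
#'   per-bin mean depth.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param library_size named numeric vector of total mapped reads per
#'   sample.
#' @param normalized logical; TRUE after [normalize_coverage()].
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(depth, bin_size, chrom_lengths, library_size,
                           normalized = FALSE) {
  stopifnot(all(names(depth) %in% names(library_size)) || normalized)
  for (s in names(depth)) for (chr in names(depth[[s]])) {
    if (any(depth[[s]][[chr]] < 0)) stop("negative depth for ", s, " on ", chr)
  }
  structure(list(depth = depth, bin_size = bin_size,
                 chrom_lengths = chrom_lengths, library_size = library_size,
                 samples = names(depth), normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d sample(s), %d chromosome(s), bin = %d bp%s\n",
              length(x$samples), length(x$chrom_lengths), x$bin_size,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

# widths of the bins tiling one chromosome
bin_widths <- function(chrom_len, bin_size) {
  n <- ceiling(chrom_len / bin_size)
  w <- rep(bin_size, n)
  w[n] <- chrom_len - (n - 1) * bin_size
  w
}

#' Write / read binned coverage as bedGraph
#'
#' One bedGraph per sample (`<sample>.bedgraph`, 0-based half-open
#' intervals) plus a `library_sizes.tsv` sidecar in the same directory.
#'
#' @param track [coverage_track()].
#' @param dir output directory (created if needed).
#' @export
write_coverage <- function(track, dir) {
  op <- options(scipen = 15)
  on.exit(options(op))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in track$samples) {
    lines <- character(0)
    for (chr in names(track$depth[[s]])) {
      v <- track$depth[[s]][[chr]]
      w <- bin_widths(track$chrom_lengths[[chr]], track$bin_size)
      start0 <- cumsum(c(0, w[-length(w)]))
      lines <- c(lines, paste(chr, start0, start0 + w, format(v, trim = TRUE, scientific = FALSE),
                              sep = "\t"))
    }
    writeLines(lines, file.path(dir, paste0(s, ".bedgraph")))
  }
  utils::write.table(
    data.frame(sample_id = track$samples,
               library_size = unname(track$library_size[track$samples])),
    file.path(dir, "library_sizes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_coverage
#' @param sample_sheet sample sheet; one bedGraph per sheet sample must
#'   exist in `dir`.
#' @return [coverage_track()].
#' @export
read_coverage <- function(dir, sample_sheet) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  lib_path <- file.path(dir, "library_sizes.tsv")
  lib <- if (file.exists(lib_path)) {
    tb <- utils::read.delim(lib_path, stringsAsFactors = FALSE)
    stats::setNames(tb$library_size, tb$sample_id)
  } else stats::setNames(rep(NA_real_, nrow(sample_sheet)), sample_sheet$sample_id)
  depth <- list()
  bin_size <- NULL
  chrom_lengths <- integer(0)
  for (s in sample_sheet$sample_id) {
    f <- file.path(dir, paste0(s, ".bedgraph"))
    if (!file.exists(f)) stop("no coverage file for sample ", s, ": ", f)
    bg <- utils::read.table(f, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    widths <- bg$end - bg$start
    bs <- max(widths)
    if (is.null(bin_size)) bin_size <- bs
    else if (bs != bin_size) stop("inconsistent bin size across samples")
    depth[[s]] <- lapply(split(bg, bg$chrom), function(d) d$value[order(d$start)])
    lens <- vapply(split(bg$end, bg$chrom), max, numeric(1))
    for (chr in names(lens))
      chrom_lengths[chr] <- max(chrom_lengths[chr] %||% 0L, lens[[chr]], na.rm = TRUE)
  }
  coverage_track(depth, bin_size, chrom_lengths, lib)
}

#' Read coding gene models from GFF3 + FASTA
#'
#' CDS features are grouped by their `Parent` (falling back to `ID`),
#' concatenated in translation order and reverse-complemented for
#' minus-strand genes. Genes violating the coding invariants (length not
#' divisible by 3, missing ATG start, internal stop codon) are skipped
#' with a warning.
#'
#' @param gff_path GFF3 path.
#' @param fasta_path reference FASTA path; contig names must match GFF
#'   seqids.
#' @return list of gene models, each a list with `gene_id`, `chrom`,
#'   `strand`, `cds` (data.frame `start`, `end`, 1-based inclusive) and
#'   `cds_seq`; attribute `n_skipped` counts excluded genes.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(sapply(as.list(cds$Parent), function(p)
    if (length(p) > 0) p[[1]] else NA_character_))
  id_col <- if (!is.null(cds$ID)) as.character(cds$ID) else rep(NA_character_, length(cds))
  key <- ifelse(is.na(parent) | parent == "", id_col, parent)
  genes <- list()
  n_skipped <- 0L
  for (g in unique(key)) {
    rows <- which(key == g)
    chrom <- as.character(GenomicRanges::seqnames(cds))[rows[1]]
    strand <- as.character(BiocGenerics::strand(cds))[rows[1]]
    st <- BiocGenerics::start(cds)[rows]
    en <- BiocGenerics::end(cds)[rows]
    ord <- order(st)
    st <- st[ord]; en <- en[ord]
    if (!chrom %in% names(ref)) {
      warning("gene ", g, ": seqid ", chrom, " not in FASTA; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    seqs <- vapply(seq_along(st), function(i)
      as.character(Biostrings::subseq(ref[[chrom]], st[i], en[i])), character(1))
    spliced <- paste(seqs, collapse = "")
    if (strand == "-") spliced <- revcomp(spliced)
    if (nchar(spliced) %% 3 != 0) {
      warning("gene ", g, ": CDS length not divisible by 3; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    codons <- split_codons(spliced)
    aa <- codon_aa(codons)
    if (codons[1] != "ATG" || any(aa[-length(aa)] == "*")) {
      warning("gene ", g, ": broken ORF (start codon / internal stop); skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    genes[[g]] <- list(gene_id = g, chrom = chrom, strand = strand,
                       cds = data.frame(start = st, end = en), cds_seq = spliced)
  }
  attr(genes, "n_skipped") <- n_skipped
  genes
}

#' Write gene models as GFF3
#'
#' Emits one `gene` and its `CDS` features per model, with `ID`/`Parent`
#' attributes that [read_gene_models()] groups on.
#'
#' @param genes list of gene models.
#' @param path output GFF3 path.
#' @export
write_gene_models <- function(genes, path) {
  op <- options(scipen = 15)
  on.exit(options(op))
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines,
               paste(g$chrom, "neosexscan", "gene", min(g$cds$start), max(g$cds$end),
                     ".", g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"))
    # frame of each CDS piece in translation order
    ord <- order(g$cds$start)
    if (identical(g$strand, "-")) ord <- rev(ord)
    lens <- (g$cds$end - g$cds$start + 1)[ord]
    phase <- (3 - (cumsum(c(0, lens[-length(lens)])) %% 3)) %% 3
    for (k in seq_along(ord)) {
      i <- ord[k]
      lines <- c(lines,
                 paste(g$chrom, "neosexscan", "CDS", g$cds$start[i], g$cds$end[i],
                       ".", g$strand, phase[k],
                       paste0("ID=", g$gene_id, ".cds", k, ";Parent=", g$gene_id),
                       sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write window statistics as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so a window (chrom, 1, 500000) becomes `chrom 0 500000`.
#'
#' @param stats data.frame with `chrom`, `start`, `end`, `value` (plus any
#'   extra columns, appended after value).
#' @param bed_path output path.
#' @export
write_windows <- function(stats, bed_path) {
  op <- options(scipen = 15)
  on.exit(options(op))
  extra <- setdiff(names(stats), c("chrom", "start", "end", "value"))
  df <- data.frame(chrom = stats$chrom, start = stats$start - 1L, end = stats$end,
                   value = stats$value)
  for (cc in extra) df[[cc]] <- stats[[cc]]
  utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}

#' @rdname write_windows
#' @param col_names names for columns after `end` (default `value`, then
#'   `n_informative`, `flag` if present).
#' @return data.frame with 1-based inclusive `start`.
#' @export
read_windows <- function(bed_path, col_names = NULL) {
  df <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end")
  if (is.null(col_names))
    col_names <- c("value", "n_informative", "flag")[seq_len(ncol(df) - 3)]
  names(df) <- c(base, col_names)
  df$start <- df$start + 1L
  df
}

#' Assembly layout of ordered blocks
#'
#' Ordered, non-overlapping blocks per chromosome with an orientation;
#' inverted blocks mirror coordinates, mapping p to start + end - p (the
#' supercontig-reorientation convention for mis-assembled reference
#' chromosomes).
#'
#' @param chrom,start,end,orientation equal-length vectors; orientation in
#'   `{"forward", "inverted"}`.
#' @return data.frame of class `assembly_layout`.
#' @export
assembly_layout <- function(chrom, start, end, orientation) {
  stopifnot(all(orientation %in% c("forward", "inverted")), all(start <= end))
  df <- data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
                   orientation = orientation, stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
      stop("overlapping blocks on ", ch)
  }
  class(df) <- c("assembly_layout", "data.frame")
  df
}

#' Remap positions through an assembly layout
#'
#' Forward blocks map positions identically; inverted blocks mirror them
#' (p -> start + end - p). Positions outside every block are returned NA
#' (unplaced) and counted in the `n_unplaced` attribute.
#'
#' @param chrom,pos equal-length chromosome labels and 1-based positions.
#' @param layout [assembly_layout()].
#' @return numeric vector of remapped positions, with attribute
#'   `n_unplaced`.
#' @export
apply_assembly_layout <- function(chrom, pos, layout) {
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(layout))) {
    b <- layout[i, ]
    hit <- chrom == b$chrom & pos >= b$start & pos <= b$end
    out[hit] <- if (b$orientation == "inverted") b$start + b$end - pos[hit] else pos[hit]
  }
  attr(out, "n_unplaced") <- sum(is.na(out) & !is.na(pos))
  out
}
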