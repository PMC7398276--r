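# allc / BED / TPM I/O, strand merging, QC, annotation filters, gene linking.
#
# Coordinate conventions (centralised here and in intervals.R): allc
# positions are 1-based; all interval tables are BED 0-based half-open.

ALLC_COLS <- c("chrom", "pos", "strand", "context", "mc", "cov")

#' Read a per-cytosine count table (allc dialect)
#'
#' Tab-separated, no header, >= 6 columns: chromosome, 1-based position,
#' strand, trinucleotide context (starting at the cytosine), methylated
#' read count, total read count. A 7th 0/1 column, if present, is accepted
#' and ignored. Gzip is handled transparently.
#'
#' @param path file path (.tsv or .tsv.gz)
#' @return `data.table` with columns chrom, pos, strand, context, mc, cov
#' @export
read_allc <- function(path) {
  con0 <- gzfile(path, "rt")
  first <- readLines(con0, n = 1)
  close(con0)
  if (!length(first)) stop("empty allc file: ", path)
  nfld <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (nfld < 6) stop("allc file ", path, " has fewer than 6 columns")
  cls <- c("character", "integer", "character", "character",
           "integer", "integer", rep("NULL", nfld - 6))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  x <- tryCatch(
    read.table(con, sep = "\t", header = FALSE, quote = "",
               comment.char = "", stringsAsFactors = FALSE,
               colClasses = cls),
    error = function(e) stop("failed to parse allc file ", path, ": ",
                             conditionMessage(e)))
  names(x) <- ALLC_COLS
  dt <- as.data.table(x)
  validate_allc(dt, path)
  dt
}

validate_allc <- function(dt, what = "allc table") {
  bad <- which(dt$pos <= 0)
  if (length(bad)) stop(what, ": non-positive position at line ", bad[1])
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) stop(what, ": unknown strand at line ", bad[1])
  bad <- which(dt$mc > dt$cov | dt$mc < 0)
  if (length(bad)) stop(what, ": mc > cov (or mc < 0) at line ", bad[1])
  invisible(dt)
}

#' Write an allc table (inverse of [read_allc()])
#' @param dt allc table
#' @param path output path; gzip when it ends in `.gz`
#' @export
write_allc <- function(dt, path) {
  validate_allc(dt)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(dt[, ALLC_COLS, with = FALSE], con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED (3+ columns, tab-separated, no header)
#' @param path file path
#' @export
read_bed <- function(path) {
  x <- read.table(gzfile(path), sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  validate_bed(as.data.table(x))
}

#' @rdname read_bed
#' @param x BED table
#' @export
write_bed <- function(x, path) {
  validate_bed(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Combine CpG dyad strands
#'
#' A CpG dyad measured at (+ strand, position p) and (- strand, p + 1)
#' becomes one record at p with mc and cov summed. Lone CG rows (either
#' strand) and all non-CG rows pass through untouched. Input must be sorted
#' by (chrom, pos).
#'
#' @param dt allc table
#' @return allc table with dyads collapsed onto the + strand position
#' @export
merge_strand_cg <- function(dt) {
  is_cg <- substr(dt$context, 1, 2) == "CG"
  cg_plus <- dt[is_cg & strand == "+"]
  cg_minus <- dt[is_cg & strand == "-"]
  other <- dt[!is_cg]
  if (nrow(cg_plus) && nrow(cg_minus)) {
    cg_minus[, key_pos := pos - 1L]
    mi <- cg_minus[cg_plus, on = c(chrom = "chrom", key_pos = "pos"),
                   which = TRUE]
    matched <- !is.na(mi)
    cg_plus[matched, `:=`(mc = mc + cg_minus$mc[mi[matched]],
                          cov = cov + cg_minus$cov[mi[matched]])]
    lone_minus <- cg_minus[!seq_len(.N) %in% mi[matched]]
    lone_minus[, key_pos := NULL]
  } else {
    lone_minus <- cg_minus
  }
  out <- rbind(cg_plus, lone_minus, other)
  setorder(out, chrom, pos)
  out[]
}

#' Quality-control metrics for one WGBS sample
#'
#' Non-conversion rate is the pooled methylated fraction of the lambda
#' spike-in. Mean coverage is reads per cytosine with CpG strands combined.
#' When a partner replicate is supplied, `replicate_r` is the Pearson
#' correlation of per-site mCG fractions over strand-merged CpG sites
#' covered by at least `cov_min` reads in both replicates.
#'
#' @param allc sample allc table
#' @param lambda lambda spike-in allc table (required, non-empty)
#' @param partner optional partner-replicate allc table
#' @param cov_min minimum per-site coverage for the replicate correlation
#' @return object of class `QCReport` (a list)
#' @export
compute_qc <- function(allc, lambda, partner = NULL, cov_min = 10) {
  if (is.null(lambda) || nrow(lambda) == 0 || sum(lambda$cov) == 0)
    stop("empty lambda spike-in table; cannot estimate non-conversion")
  nonconv <- sum(lambda$mc) / sum(lambda$cov)
  merged <- merge_strand_cg(allc)
  out <- list(mean_coverage = mean(merged$cov),
              nonconversion_rate = nonconv,
              replicate_r = NULL)
  if (!is.null(partner)) {
    a <- merge_strand_cg(allc); a <- a[substr(context, 1, 2) == "CG"]
    b <- merge_strand_cg(partner); b <- b[substr(context, 1, 2) == "CG"]
    ab <- merge(a[, .(chrom, pos, mc1 = mc, cov1 = cov)],
                b[, .(chrom, pos, mc2 = mc, cov2 = cov)],
                by = c("chrom", "pos"))
    ab <- ab[cov1 >= cov_min & cov2 >= cov_min]
    out$replicate_r <- if (nrow(ab) >= 2)
      cor(ab$mc1 / ab$cov1, ab$mc2 / ab$cov2) else NA_real_
  }
  structure(out, class = "QCReport")
}

#' Filter transposons to the mappable subset
#'
#' Keeps transposable elements containing at least `min_cg` CpG sites of
#' which at least `min_frac` (inclusive at the boundary) are covered by
#' >= `cov_min` reads in every sample (replicates combined, strands
#' merged).
#'
#' @param transposons BED table
#' @param cg_samples list of strand-merged CG allc tables, one per sample
#'   (replicates already combined)
#' @param min_cg minimum CpG sites per element (default 2)
#' @param min_frac minimum well-covered fraction (default 0.6)
#' @param cov_min coverage threshold (default 10)
#' @return filtered BED table
#' @export
filter_mappable_transposons <- function(transposons, cg_samples,
                                        min_cg = 2, min_frac = 0.6,
                                        cov_min = 10) {
  if (!length(cg_samples)) stop("need at least one sample")
  sites <- cg_samples[[1]][, .(chrom, pos)]
  mincov <- cg_samples[[1]]$cov
  for (s in cg_samples[-1]) {
    m <- merge(sites[, .(chrom, pos, i = .I)],
               s[, .(chrom, pos, cov)], by = c("chrom", "pos"), all.x = TRUE)
    setorder(m, i)
    mincov <- pmin(mincov, fifelse(is.na(m$cov), 0L, m$cov))
  }
  idx <- point_interval_index(sites$chrom, sites$pos, transposons)
  ok_site <- mincov >= cov_min
  keep <- rep(FALSE, nrow(transposons))
  if (any(!is.na(idx))) {
    tab <- data.table(te = idx[!is.na(idx)], ok = ok_site[!is.na(idx)])
    agg <- tab[, .(n = .N, frac = mean(ok)), by = te]
    keep[agg$te] <- agg$n >= min_cg & agg$frac >= min_frac
  }
  transposons[keep]
}

#' Keep genes expressed in a minimum fraction of samples
#'
#' Retains genes with TPM > 0 in at least `min_fraction` of samples
#' (boundary inclusive). With `ontology_clean = TRUE`, genes whose names
#' start with "Rik" or "Gm" followed by a digit are dropped (ill-defined
#' ontology).
#'
#' @param tpm numeric matrix or data.frame, genes x samples, rownames =
#'   gene names
#' @param min_fraction minimum fraction of samples with non-zero TPM
#' @param ontology_clean drop ill-defined gene names
#' @return character vector of retained gene names
#' @export
filter_expressed_genes <- function(tpm, min_fraction = 0.1,
                                   ontology_clean = FALSE) {
  if (is.null(dim(tpm)) || ncol(tpm) < 1) stop("TPM table needs >= 1 sample")
  m <- as.matrix(tpm)
  keep <- rowMeans(m > 0) >= min_fraction
  genes <- rownames(m)[keep]
  if (ontology_clean) genes <- genes[!grepl("^(Rik|Gm[0-9])", genes)]
  genes
}

#' Link regions to their nearest expressed-gene TSS
#'
#' Each region maps to exactly one gene: the TSS nearest to the region
#' boundary (distance 0 if the TSS lies inside). Equidistant TSSs break to
#' the lower coordinate.
#'
#' @param regions BED table
#' @param tss `data.table` with columns chrom, pos (1-based TSS), gene
#' @return `data.table`: the regions plus `gene` and `distance`
#' @export
link_regions_to_genes <- function(regions, tss) {
  if (!nrow(tss)) stop("empty gene/TSS set")
  out <- copy(as.data.table(regions))
  out[, `:=`(gene = NA_character_, distance = NA_real_)]
  for (cn in unique(out$chrom)) {
    t <- tss[chrom == cn][order(pos)]
    ri <- which(out$chrom == cn)
    if (!nrow(t)) next
    t0 <- t$pos - 1  # 0-based coordinate of the TSS base
    for (i in ri) {
      s <- out$start[i]; e <- out$end[i]
      d <- ifelse(t0 >= s & t0 < e, 0,
                  ifelse(t0 < s, s - t0, t0 - (e - 1)))
      j <- which(d == min(d))[1]  # ties: lowest coordinate (t sorted by pos)
      out$gene[i] <- t$gene[j]
      out$distance[i] <- d[j]
    }
  }
  if (anyNA(out$gene)) {
    # chromosomes with no TSS: fall back to genome-wide nearest is not
    # meaningful; keep NA but warn
    warning("some regions lie on chromosomes without any TSS; gene = NA")
  }
  out[]
}

#' Read a TPM matrix (genes x samples, TSV with header and gene-name
#' first column)
#' @param path file path
#' @export
read_tpm <- function(path) {
  x <- read.table(gzfile(path), sep = "\t", header = TRUE, row.names = 1,
                  check.names = FALSE)
  as.matrix(x)
}
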