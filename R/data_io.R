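# Delimited-text and VCF input/output for the pipeline. Coordinates are
# 1-based inclusive (VCF convention) throughout; the missing token is "NA"
# in text tables and "./." in VCF; delimiter auto-detection is limited to
# tab and comma.

detect_delim <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (!length(line1)) stop("empty file: ", path)
  n_tab <- lengths(regmatches(line1, gregexpr("\t", line1)))
  n_com <- lengths(regmatches(line1, gregexpr(",", line1)))
  if (n_tab == 0 && n_com == 0)
    stop("cannot detect delimiter (expected tab or comma): ", path)
  if (n_tab >= n_com) "\t" else ","
}

# internal constructor; assumes fields already validated
new_pheno_table <- function(df, timepoints, load_report = NULL) {
  df$timepoint <- factor(as.character(df$timepoint), levels = timepoints)
  df <- df[order(df$clone, df$block, df$tree, as.integer(df$timepoint)), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, timepoints = timepoints, load_report = load_report,
            class = c("pheno_table", "data.frame"))
}

#' Construct a validated phenotype table
#'
#' A phenotype table holds one record per tree per time point: clone ID,
#' block ID, tree (cutting) ID, an ordered time-point label and a positive
#' height in cm. Missing measurements are absent records, never sentinel
#' values.
#'
#' @param df Data frame with columns \code{clone}, \code{block},
#'   \code{tree}, \code{timepoint}, \code{height}.
#' @param timepoints Character vector giving the time-point labels in
#'   definition order; defaults to their order of first appearance.
#' @return A \code{pheno_table} (a data frame with a \code{timepoints}
#'   attribute).
#' @export
pheno_table <- function(df, timepoints = NULL) {
  req <- c("clone", "block", "tree", "timepoint", "height")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[req]
  for (col in c("clone", "block", "tree", "timepoint"))
    df[[col]] <- as.character(df[[col]])
  if (!is.numeric(df$height)) {
    h <- suppressWarnings(as.numeric(df$height))
    bad <- which(is.na(h) & !is.na(df$height))
    if (length(bad))
      stop("non-numeric height at row ", bad[1])
    df$height <- h
  }
  bad <- which(!is.finite(df$height) | df$height <= 0)
  if (length(bad))
    stop("height must be finite and positive; violation at row ", bad[1])
  if (is.null(timepoints)) timepoints <- unique(df$timepoint)
  unknown <- setdiff(df$timepoint, timepoints)
  if (length(unknown))
    stop("time-point label(s) not in the configured order: ",
         paste(unknown, collapse = ", "))
  key <- paste(df$clone, df$block, df$tree, df$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (clone, block, tree, timepoint) record at row ", dup[1])
  new_pheno_table(df, timepoints)
}

#' Read a phenotype table from delimited text
#'
#' Accepts either long format (columns \code{clone}, \code{block},
#' \code{tree}, \code{timepoint}, \code{height}) or wide format (columns
#' \code{clone}, \code{block}, \code{tree} plus one height column per
#' time-point label). Wide input is melted to long form; records with an
#' empty height cell are dropped and counted in the load report (attribute
#' \code{load_report}).
#'
#' @param path Path to a tab- or comma-delimited text file with a header.
#' @param timepoint_order Optional label order; defaults to
#'   \code{T1}..\code{T8} for wide input and to order of appearance for
#'   long input.
#' @return A \code{\link{pheno_table}}.
#' @export
read_phenotype_table <- function(path, timepoint_order = NULL) {
  sep <- detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", quote = "\"")
  req <- c("clone", "block", "tree")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  n_dropped <- 0L
  if (all(c("timepoint", "height") %in% names(raw))) {
    long <- raw[c("clone", "block", "tree", "timepoint", "height")]
    blank <- is.na(long$height) |
      (is.character(long$height) & trimws(long$height) == "")
    n_dropped <- sum(blank)
    long <- long[!blank, , drop = FALSE]
    tp <- timepoint_order
  } else {
    tp <- if (is.null(timepoint_order)) paste0("T", 1:8) else timepoint_order
    have <- intersect(tp, names(raw))
    if (!length(have))
      stop("missing required column(s): timepoint/height or wide height ",
           "columns named by the time-point labels (",
           paste(tp, collapse = ", "), ")")
    if (!all(tp %in% names(raw)))
      stop("missing required column(s): ",
           paste(setdiff(tp, names(raw)), collapse = ", "))
    pieces <- lapply(tp, function(t)
      data.frame(clone = raw$clone, block = raw$block, tree = raw$tree,
                 timepoint = t, height = raw[[t]],
                 stringsAsFactors = FALSE))
    long <- do.call(rbind, pieces)
    blank <- is.na(long$height) |
      (is.character(long$height) & trimws(long$height) == "")
    n_dropped <- sum(blank)
    long <- long[!blank, , drop = FALSE]
  }
  out <- pheno_table(long, timepoints = tp)
  attr(out, "load_report") <- list(n_dropped = n_dropped,
                                   n_records = nrow(out))
  out
}

#' Write a phenotype table to tab-separated text (long format)
#'
#' @param pheno A \code{\link{pheno_table}}.
#' @param path Output path.
#' @export
write_phenotype_table <- function(pheno, path) {
  stopifnot(inherits(pheno, "pheno_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#fields=clone\tblock\ttree\ttimepoint\theight", con)
  utils::write.table(as.data.frame(pheno), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

new_geno_matrix <- function(clones, loci, calls) {
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(clones, loci$snp_id)
  structure(list(clones = clones, loci = loci, calls = calls),
            class = "geno_matrix")
}

subset_geno <- function(geno, snp_idx) {
  new_geno_matrix(geno$clones, geno$loci[snp_idx, , drop = FALSE],
                  geno$calls[, snp_idx, drop = FALSE])
}

#' Read a clones-by-SNPs genotype table
#'
#' One row per SNP: \code{snp_id}, \code{chrom}, \code{pos} (1-based bp),
#' \code{seg_type}, then one genotype-class column per clone. Calls are
#' normalized to alphabetical allele order; the missing token maps to
#' \code{NA}; any other string not matching a genotype class is an error.
#' Every non-missing call must belong to the offspring class set of the
#' SNP's segregation type. Loci are sorted by (chrom, pos) on load.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param missing_token String encoding a missing call (default
#'   \code{"NA"}).
#' @return A \code{geno_matrix}: list with \code{clones}, \code{loci}
#'   (data frame \code{snp_id}, \code{chrom}, \code{pos}, \code{seg_type})
#'   and \code{calls} (clones x SNPs character matrix, \code{NA} =
#'   missing).
#' @export
read_genotype_table <- function(path, missing_token = "NA") {
  sep <- detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", quote = "\"",
                           colClasses = "character", na.strings = NULL)
  req <- c("snp_id", "chrom", "pos", "seg_type")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  clones <- setdiff(names(raw), req)
  if (!length(clones)) stop("no clone genotype columns found")
  dup <- which(duplicated(raw$snp_id))
  if (length(dup))
    stop("duplicate snp_id: ", raw$snp_id[dup[1]])
  pos <- suppressWarnings(as.integer(raw$pos))
  if (any(is.na(pos) | pos < 1))
    stop("pos must be a positive 1-based integer")
  seg <- normalize_seg_type(raw$seg_type)
  bad_seg <- setdiff(unique(seg), cross_types()$code)
  if (length(bad_seg))
    stop("unknown segregation type: ", paste(bad_seg, collapse = ", "))
  calls <- matrix(NA_character_, nrow = length(clones), ncol = nrow(raw))
  for (s in seq_len(nrow(raw))) {
    v <- as.character(raw[s, clones])
    v[v == missing_token] <- NA_character_
    v <- normalize_geno_class(v)
    allowed <- cross_classes(seg[s])
    bad <- which(!is.na(v) & !(v %in% allowed))
    if (length(bad))
      stop("call '", v[bad[1]], "' at SNP ", raw$snp_id[s], ", clone ",
           clones[bad[1]], " is inconsistent with segregation type ",
           seg[s])
    calls[, s] <- v
  }
  loci <- data.frame(snp_id = raw$snp_id, chrom = raw$chrom, pos = pos,
                     seg_type = seg, stringsAsFactors = FALSE)
  new_geno_matrix(clones, loci, calls)
}

#' Write a genotype matrix to tab-separated text
#'
#' @param geno A \code{geno_matrix}.
#' @param path Output path.
#' @param missing_token String to write for missing calls.
#' @export
write_genotype_table <- function(geno, path, missing_token = "NA") {
  stopifnot(inherits(geno, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#fields=snp_id\tchrom\tpos\tseg_type\t",
                    paste(geno$clones, collapse = "\t")), con)
  calls <- t(geno$calls)
  calls[is.na(calls)] <- missing_token
  out <- cbind(geno$loci, as.data.frame(calls, stringsAsFactors = FALSE))
  names(out) <- c("snp_id", "chrom", "pos", "seg_type", geno$clones)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Derive a genotype matrix from a VCF with per-call quality control
#'
#' Reads a VCF 4.x file containing both parents and the clone offspring,
#' infers each record's cross type from the parental genotype pair, and
#' accepts per-sample calls only when they pass the depth and quality
#' thresholds: each allele of a heterozygous call needs
#' \code{min_het_allele_depth} supporting reads (from \code{AD}), a
#' homozygous call needs \code{min_hom_depth} reads on its allele, and all
#' calls need \code{GQ >= min_genotype_quality}. Failing calls become
#' missing. Records whose parental pair is non-segregating, not
#' representable with three alleles, or whose parental call fails QC are
#' dropped and counted in the drop report (attribute \code{vcf_report}).
#' Offspring calls outside the cross's expected class set are set to
#' missing and counted.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param parent_ids Character vector of length 2: female then male sample
#'   ID.
#' @param qc A \code{\link{qc_thresholds}} object (per-call thresholds
#'   only; per-SNP filters are applied separately by
#'   \code{\link{filter_snps}}).
#' @return A \code{geno_matrix} over the non-parent samples.
#' @export
read_vcf_genotypes <- function(path, parent_ids, qc = qc_thresholds()) {
  stopifnot(length(parent_ids) == 2)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing_parents <- setdiff(parent_ids, samples)
  if (length(missing_parents))
    stop("parent sample absent from VCF: ",
         paste(missing_parents, collapse = ", "))
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  for (f in c("GQ", "AD"))
    if (!(f %in% fmt))
      stop("VCF lacks required per-genotype field: ", f)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gq <- suppressWarnings(
    apply(vcfR::extract.gt(vcf, element = "GQ"), 2, as.numeric))
  if (is.null(dim(gq))) gq <- matrix(gq, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
  clones <- setdiff(samples, parent_ids)

  parse_gt <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NULL)
    al <- strsplit(gsub("\\|", "/", g), "/")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NULL)
    sort(as.integer(al))
  }
  call_ok <- function(alleles, ad_str, gq_val) {
    if (is.na(gq_val) || gq_val < qc$min_genotype_quality) return(FALSE)
    if (is.na(ad_str)) return(FALSE)
    depths <- suppressWarnings(as.integer(strsplit(ad_str, ",")[[1]]))
    if (anyNA(depths)) return(FALSE)
    idx <- alleles + 1L
    if (any(idx > length(depths))) return(FALSE)
    if (alleles[1] == alleles[2])
      depths[idx[1]] >= qc$min_hom_depth
    else
      all(depths[idx] >= qc$min_het_allele_depth)
  }

  n_rec <- nrow(gt)
  kept <- logical(n_rec)
  drop_nonseg <- 0L; drop_parent <- 0L
  mendel_masked <- 0L
  loci_list <- vector("list", n_rec)
  calls_list <- vector("list", n_rec)
  chroms <- vcfR::getCHROM(vcf)
  poss <- vcfR::getPOS(vcf)
  ids <- vcfR::getID(vcf)
  for (r in seq_len(n_rec)) {
    pg <- lapply(parent_ids, function(s) parse_gt(gt[r, s]))
    pok <- vapply(seq_along(parent_ids), function(i) {
      !is.null(pg[[i]]) && call_ok(pg[[i]], ad[r, parent_ids[i]],
                                   gq[r, parent_ids[i]])
    }, logical(1))
    if (!all(pok)) { drop_parent <- drop_parent + 1L; next }
    pstr <- vapply(pg, function(a) paste(a, collapse = ""), "")
    ct <- tryCatch(infer_cross_type(pstr[1], pstr[2]),
                   error = function(e) NULL)
    if (is.null(ct) || !ct$segregating) {
      drop_nonseg <- drop_nonseg + 1L
      next
    }
    cl_calls <- rep(NA_character_, length(clones))
    for (i in seq_along(clones)) {
      s <- clones[i]
      og <- parse_gt(gt[r, s])
      if (is.null(og)) next
      if (!call_ok(og, ad[r, s], gq[r, s])) next
      cls <- map_geno_class(paste(og, collapse = ""), ct$mapping)
      if (is.na(cls) || !(cls %in% ct$classes)) {
        mendel_masked <- mendel_masked + 1L
        next
      }
      cl_calls[i] <- cls
    }
    kept[r] <- TRUE
    id <- ids[r]
    if (is.na(id) || id == ".")
      id <- paste0(chroms[r], "_", poss[r])
    loci_list[[r]] <- data.frame(snp_id = id, chrom = chroms[r],
                                 pos = poss[r], seg_type = ct$code,
                                 stringsAsFactors = FALSE)
    calls_list[[r]] <- cl_calls
  }
  if (!any(kept))
    stop("no usable segregating records in VCF")
  loci <- do.call(rbind, loci_list[kept])
  calls <- do.call(cbind, calls_list[kept])
  out <- new_geno_matrix(clones, loci, matrix(calls, nrow = length(clones)))
  attr(out, "vcf_report") <- list(
    n_records = n_rec, n_kept = sum(kept),
    dropped_non_segregating = drop_nonseg,
    dropped_parent_call = drop_parent,
    offspring_calls_masked = mendel_masked)
  out
}

scan_result_columns <- function(timepoints) {
  c("snp_id", "chrom", "pos", "seg_type", "F", "df1", "df2", "p",
    "neg_log10_p", "r2_percent", paste0("effect_", timepoints),
    "n_used", "significant")
}

#' Write scan results to tab-separated text
#'
#' Emits one line per SNP with the association statistics, per-time-point
#' effects and significance flag, preceded by a \code{#fields=} header and,
#' when available, a \code{#p_threshold=} line recording the scan's
#' significance threshold. Numeric values are written with 12 significant
#' digits so that a write/read round trip is lossless at that precision.
#'
#' @param results A \code{snp_scan} data frame (from
#'   \code{\link{scan_multivariate}}).
#' @param path Output path.
#' @export
write_scan_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    stop("results must be non-empty")
  cols <- names(results)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#fields=", paste(cols, collapse = "\t")), con)
  thr <- attr(results, "p_threshold")
  if (!is.null(thr))
    writeLines(paste0("#p_threshold=", formatC(thr, digits = 12,
                                               format = "g")), con)
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x))
      formatC(x, digits = 12, format = "g")
    else as.character(x)
  }
  body <- do.call(cbind, lapply(results, fmt))
  body[is.na(do.call(cbind, lapply(results, as.character)))] <- "NA"
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read back scan results written by \code{\link{write_scan_results}}
#'
#' @param path Path to a scan-results file.
#' @return A data frame; the recorded threshold (if any) is restored as
#'   attribute \code{p_threshold}.
#' @export
read_scan_results <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#fields=")]
  if (!length(hdr)) stop("missing #fields= header: ", path)
  cols <- strsplit(sub("^#fields=", "", hdr[1]), "\t")[[1]]
  thr_line <- lines[startsWith(lines, "#p_threshold=")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t",
                          col.names = cols, stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$chrom <- as.character(df$chrom)
  if (length(thr_line))
    attr(df, "p_threshold") <- as.numeric(sub("^#p_threshold=", "",
                                              thr_line[1]))
  df
}

#' Read QTL intervals from BED-like text
#'
#' Columns \code{chrom}, \code{start}, \code{end}, \code{label}; 1-based
#' inclusive coordinates so positions compare directly with SNP positions.
#'
#' @param path Path to a tab- or comma-delimited file with a header.
#' @return A data frame of intervals with \code{start <= end}.
#' @export
read_qtl_intervals <- function(path) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  req <- c("chrom", "start", "end", "label")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(df$start > df$end)) stop("interval with start > end")
  df[req]
}
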