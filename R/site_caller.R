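## De novo candidate-site detection: a per-position base-distribution pileup
## over filtered alignments, threshold-based variant calling against the
## reference, and gene-strand assignment from annotation.

#' Read and quality filter settings for the pileup
#'
#' Bundles the read-level filters applied before any base is counted.
#' Defaults are the strict settings used for de novo editing-site discovery
#' from uniquely mapped, properly paired reads: base quality >= 30, mapping
#' quality >= 60 (the unique-mapping MAPQ of spliced aligners such as
#' hisat2), duplicates and multimappers excluded, concordant pairs only,
#' and a site called from as little as one read of coverage and one
#' variant-supporting read.
#'
#' @param min_base_quality Minimum phred base quality for a base to be
#'   counted (default 30).
#' @param min_mapping_quality Minimum MAPQ for a read to contribute
#'   (default 60).
#' @param min_coverage Minimum filtered coverage for a position to be
#'   eligible as a call (default 1).
#' @param min_variant_reads Minimum reads supporting a non-reference base
#'   (default 1).
#' @param exclude_duplicates Drop reads flagged as PCR/optical duplicates
#'   (default `TRUE`).
#' @param exclude_multimappers Drop secondary/supplementary alignments and,
#'   when `check_nh_tag`, reads whose NH tag exceeds 1 (default `TRUE`).
#' @param require_concordant_pairs Keep only reads with the proper-pair
#'   flag set (default `TRUE`).
#' @param check_nh_tag Also consult the NH tag for multimapper exclusion
#'   when present (default `TRUE`).
#' @return A `filter_config` object.
#' @export
filter_config <- function(min_base_quality = 30L,
                          min_mapping_quality = 60L,
                          min_coverage = 1L,
                          min_variant_reads = 1L,
                          exclude_duplicates = TRUE,
                          exclude_multimappers = TRUE,
                          require_concordant_pairs = TRUE,
                          check_nh_tag = TRUE) {
  num <- c(min_base_quality = min_base_quality,
           min_mapping_quality = min_mapping_quality,
           min_coverage = min_coverage,
           min_variant_reads = min_variant_reads)
  if (any(is.na(num)) || any(num < 0))
    stop("filter thresholds must be non-negative", call. = FALSE)
  structure(list(
    min_base_quality = as.integer(min_base_quality),
    min_mapping_quality = as.integer(min_mapping_quality),
    min_coverage = as.integer(min_coverage),
    min_variant_reads = as.integer(min_variant_reads),
    exclude_duplicates = isTRUE(exclude_duplicates),
    exclude_multimappers = isTRUE(exclude_multimappers),
    require_concordant_pairs = isTRUE(require_concordant_pairs),
    check_nh_tag = isTRUE(check_nh_tag)
  ), class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Pileup filter settings:\n")
  cat("  min base quality   ", x$min_base_quality, "\n")
  cat("  min mapping quality", x$min_mapping_quality, "\n")
  cat("  min coverage       ", x$min_coverage, "\n")
  cat("  min variant reads  ", x$min_variant_reads, "\n")
  cat("  exclude duplicates ", x$exclude_duplicates,
      " multimappers ", x$exclude_multimappers,
      " concordant only ", x$require_concordant_pairs, "\n")
  invisible(x)
}

#' Per-position base-distribution pileup from a BAM file
#'
#' Accumulates, for every covered reference position, the counts of A/C/G/T
#' among bases of reads passing the [filter_config()] filters. A read
#' contributes at a position iff it is mapped there through an aligned
#' (M/=/X) CIGAR operation — insertions, deletions and reference skips
#' contribute nothing — its MAPQ, flags and NH tag pass the read-level
#' filters, and the base quality at that position is at least
#' `min_base_quality`. When both mates of a fragment cover a position the
#' fragment contributes once: the higher-quality base wins, ties go to the
#' first mate. Ambiguous (N) bases are never counted; coverage is always
#' A+C+G+T.
#'
#' @param bam Path to a coordinate-sorted BAM file. An index (.bai) is
#'   required when `region` is given.
#' @param region Optional [GenomicRanges::GRanges] restricting the pileup.
#' @param config A [filter_config()].
#' @return A `data.table` with columns `chrom`, `pos` (1-based), `A`, `C`,
#'   `G`, `T`, `coverage`, `mean_quality` (arithmetic mean phred quality of
#'   counted bases, 2 decimals), sorted by position.
#' @export
accumulate_pileup <- function(bam, region = NULL, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (!file.exists(bam)) stop("BAM file not found: ", bam, call. = FALSE)
  has_index <- file.exists(paste0(bam, ".bai")) ||
    file.exists(sub("\\.bam$", ".bai", bam, ignore.case = TRUE))
  if (!is.null(region) && !has_index)
    stop("BAM '", bam, "' has no index; coordinate-sort and index it ",
         "(samtools sort; samtools index)", call. = FALSE)
  bf <- Rsamtools::BamFile(bam)

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (config$exclude_duplicates) FALSE else NA,
    isSecondaryAlignment = if (config$exclude_multimappers) FALSE else NA,
    isSupplementaryAlignment = if (config$exclude_multimappers) FALSE else NA,
    isProperPair = if (config$require_concordant_pairs) TRUE else NA
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "seq", "qual"),
    tag = if (config$exclude_multimappers && config$check_nh_tag) "NH"
          else character(),
    mapqFilter = config$min_mapping_quality,
    which = if (is.null(region)) GRanges() else region
  )
  if (is.null(region))
    param <- Rsamtools::ScanBamParam(
      flag = flag, what = c("qname", "flag", "seq", "qual"),
      tag = if (config$exclude_multimappers && config$check_nh_tag) "NH"
            else character(),
      mapqFilter = config$min_mapping_quality)

  gal <- tryCatch(
    GenomicAlignments::readGAlignments(bf, param = param),
    error = function(e) stop("failed to read alignments from '", bam,
                             "' (is it coordinate-sorted and indexed?): ",
                             conditionMessage(e), call. = FALSE)
  )
  mc <- S4Vectors::mcols(gal)
  if (config$exclude_multimappers && config$check_nh_tag &&
      !is.null(mc$NH)) {
    keep <- is.na(mc$NH) | mc$NH <= 1L
    gal <- gal[keep]
    mc <- S4Vectors::mcols(gal)
  }
  if (length(gal) == 0L) return(empty_pileup())

  cig <- GenomicAlignments::cigar(gal)
  ops <- c("M", "=", "X")
  rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = ops, pos = GenomicAlignments::start(gal))
  rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = ops)

  nb <- S4Vectors::elementNROWS(rref)
  rb <- unlist(rref, use.names = FALSE)
  qb <- unlist(rqry, use.names = FALSE)
  w <- IRanges::width(rb)
  if (sum(as.numeric(w)) == 0) return(empty_pileup())
  read_of_block <- rep(seq_along(gal), nb)
  rid <- rep(read_of_block, w)
  pos <- sequence(w, from = IRanges::start(rb), by = 1L)
  qidx <- sequence(w, from = IRanges::start(qb), by = 1L)

  seqs <- as.character(mc$seq)
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  allb <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  allq <- unlist(as(mc$qual, "IntegerList"), use.names = FALSE)
  lin <- offs[rid] + qidx

  dt <- data.table(
    qname = mc$qname[rid],
    first_mate = bitwAnd(mc$flag[rid], 64L) > 0L,
    chrom = as.character(seqnames(gal))[rid],
    pos = pos,
    base = allb[lin],
    qual = allq[lin]
  )
  if (!is.null(region)) {
    # `which` returns any overlapping read (possibly once per range);
    # trim bases outside the region — duplicates collapse in the
    # per-fragment step below
    rchrom <- as.character(seqnames(region))
    rs <- start(region); re <- end(region)
    keep <- rep(FALSE, nrow(dt))
    for (k in seq_along(rchrom))
      keep <- keep | (dt$chrom == rchrom[k] & dt$pos >= rs[k] &
                        dt$pos <= re[k])
    dt <- dt[keep]
  }

  # overlapping mates: one contribution per fragment per position,
  # higher base quality wins, ties to the first mate
  setorder(dt, chrom, pos, qname, -qual, -first_mate)
  dt <- unique(dt, by = c("chrom", "pos", "qname"))

  dt <- dt[qual >= config$min_base_quality & base %in% c("A", "C", "G", "T")]
  if (nrow(dt) == 0L) return(empty_pileup())

  pile <- dt[, .(
    A = sum(base == "A"), C = sum(base == "C"),
    G = sum(base == "G"), T = sum(base == "T"),
    mean_quality = round(mean(qual), 2L)
  ), by = .(chrom, pos)]
  pile[, coverage := A + C + G + T]
  setcolorder(pile, c("chrom", "pos", "A", "C", "G", "T",
                      "coverage", "mean_quality"))
  setorder(pile, chrom, pos)
  pile[]
}

empty_pileup <- function() {
  data.table(chrom = character(), pos = integer(),
             A = integer(), C = integer(), G = integer(), T = integer(),
             coverage = integer(), mean_quality = numeric())
}

## Normalize reference input to a named DNAStringSet.
load_reference <- function(reference) {
  if (is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    return(Biostrings::readDNAStringSet(reference))
  if (is.character(reference) && !is.null(names(reference)))
    return(Biostrings::DNAStringSet(reference))
  stop("reference must be a DNAStringSet, a FASTA path, or a named ",
       "character vector of sequences", call. = FALSE)
}

#' Call candidate variant positions from a pileup
#'
#' Emits one candidate site per position whose filtered coverage reaches
#' `min_coverage` and where at least one non-reference base is supported by
#' `min_variant_reads` reads. Substitutions are listed in descending
#' support order (ties broken alphabetically); the variation frequency is
#' the support of the principal (most supported) substitution divided by
#' coverage. Positions whose reference base is not A/C/G/T are skipped.
#'
#' Strand is `"*"` (unresolved) until [assign_strand()] is applied;
#' substitution codes are therefore reported on the forward reference
#' strand at this stage.
#'
#' @param pileup A pileup table from [accumulate_pileup()].
#' @param reference Reference sequences: a
#'   [Biostrings::DNAStringSet], a FASTA path, or a named character vector.
#' @param config A [filter_config()] (`min_coverage`, `min_variant_reads`).
#' @return A site-call `data.table` with columns `chrom`, `position`,
#'   `strand`, `ref`, `A`, `C`, `G`, `T`, `coverage`, `mean_quality`,
#'   `substitutions` (comma-separated), `frequency`, `is_a_to_i`.
#' @export
call_sites <- function(pileup, reference, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  ref <- load_reference(reference)
  pile <- as.data.table(pileup)
  if (nrow(pile) == 0L) return(empty_calls())
  missing_chr <- setdiff(unique(pile$chrom), names(ref))
  if (length(missing_chr))
    stop("reference lacks sequence(s): ", paste(missing_chr, collapse = ", "),
         call. = FALSE)

  pile <- pile[coverage >= config$min_coverage]
  if (nrow(pile) == 0L) return(empty_calls())

  refbase <- character(nrow(pile))
  for (ch in unique(pile$chrom)) {
    i <- which(pile$chrom == ch)
    refbase[i] <- as.character(Biostrings::extractAt(
      ref[[ch]], IRanges(pile$pos[i], pile$pos[i])))
  }
  pile[, ref := refbase]
  skipped <- !pile$ref %in% c("A", "C", "G", "T")
  if (any(skipped)) {
    message("skipping ", sum(skipped),
            " position(s) with ambiguous reference base")
    pile <- pile[!skipped]
  }
  if (nrow(pile) == 0L) return(empty_calls())

  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pile[, .(A, C, G, T)])
  # prefilter: only positions where some non-reference base could pass
  refcol <- match(pile$ref, bases)
  tmp <- cnt
  tmp[cbind(seq_len(nrow(tmp)), refcol)] <- -1L
  altmax <- pmax(tmp[, 1L], tmp[, 2L], tmp[, 3L], tmp[, 4L])
  cand <- altmax >= config$min_variant_reads
  pile <- pile[cand]
  cnt <- cnt[cand, , drop = FALSE]
  if (nrow(pile) == 0L) return(empty_calls())

  out <- vector("list", nrow(pile))
  for (i in seq_len(nrow(pile))) {
    rb <- pile$ref[i]
    alt <- setdiff(bases, rb)
    ac <- cnt[i, alt]
    ac <- ac[ac >= config$min_variant_reads]
    if (length(ac) == 0L) next
    ord <- order(-ac, names(ac))
    ac <- ac[ord]
    out[[i]] <- list(
      substitutions = paste0(rb, names(ac), collapse = ","),
      frequency = unname(ac[1L]) / pile$coverage[i]
    )
  }
  keep <- !vapply(out, is.null, TRUE)
  if (!any(keep)) return(empty_calls())
  pile <- pile[keep]
  calls <- data.table(
    chrom = pile$chrom, position = pile$pos, strand = "*",
    ref = pile$ref,
    A = pile$A, C = pile$C, G = pile$G, T = pile$T,
    coverage = pile$coverage, mean_quality = pile$mean_quality,
    substitutions = vapply(out[keep], `[[`, "", "substitutions"),
    frequency = vapply(out[keep], `[[`, 0, "frequency"),
    is_a_to_i = FALSE
  )
  setorder(calls, chrom, position)
  calls[]
}

empty_calls <- function() {
  data.table(chrom = character(), position = integer(), strand = character(),
             ref = character(), A = integer(), C = integer(), G = integer(),
             T = integer(), coverage = integer(), mean_quality = numeric(),
             substitutions = character(), frequency = numeric(),
             is_a_to_i = logical())
}

#' Assign gene strand to candidate sites and resolve A-to-I status
#'
#' Sets each call's strand to the strand of the unique overlapping
#' annotated gene. Positions covered by genes on both strands, or by no
#' gene, get strand `"*"` (unknown) and are excluded from the editing
#' analysis downstream. For minus-strand genes the substitution codes are
#' complemented, so an observed forward-strand T>C is reported as A>G.
#' `is_a_to_i` is `TRUE` iff the strand is resolved and the
#' strand-resolved substitution list contains `AG`. The overlapping gene
#' name is attached in a `gene` column (first alphabetically when several
#' same-strand genes overlap).
#'
#' @param calls A site-call table from [call_sites()].
#' @param annotation A coding annotation from [read_annotation()].
#' @return The calls table with `strand`, `gene`, `substitutions`, `ref`
#'   and `is_a_to_i` resolved.
#' @export
assign_strand <- function(calls, annotation) {
  calls <- copy(as.data.table(calls))
  if (nrow(calls) == 0L) {
    calls[, gene := character()]
    return(calls[])
  }
  hits <- annotation_hits(annotation, calls$chrom, calls$position)
  strand_of <- rep("*", nrow(calls))
  gene_of <- rep(NA_character_, nrow(calls))
  if (nrow(hits)) {
    agg <- hits[, .(strands = list(unique(strand)),
                    gene = sort(gene)[1L]), by = idx]
    one <- lengths(agg$strands) == 1L
    strand_of[agg$idx[one]] <-
      vapply(agg$strands[one], `[`, "", 1L)
    gene_of[agg$idx[one]] <- agg$gene[one]
  }
  calls[, strand := strand_of]
  calls[, gene := gene_of]
  minus <- calls$strand == "-"
  if (any(minus)) {
    calls[minus, substitutions := vapply(substitutions, function(s) {
      paste(chartr("ACGT", "TGCA", strsplit(s, ",", fixed = TRUE)[[1L]]),
            collapse = ",")
    }, "")]
    calls[minus, ref := chartr("ACGT", "TGCA", ref)]
  }
  calls[, is_a_to_i := strand %in% c("+", "-") &
          vapply(strsplit(substitutions, ",", fixed = TRUE),
                 function(s) "AG" %in% s, TRUE)]
  calls[]
}
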