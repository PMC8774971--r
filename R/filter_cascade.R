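## Filtering of candidate calls into the two analysis branches: the
## known-site-matched set (per-site differential testing) and the full
## coding A-to-I set (editing-burden comparison). The canonical order is
## strand/A-to-I classification -> coding restriction -> SNV exclusion ->
## known-site split; the filters commute, the order is fixed only so logs
## are reproducible.

#' Exclude known genomic SNV positions from candidate calls
#'
#' Drops calls whose (chromosome, position) appears in the SNV catalog.
#' Matching is positional by default — population variants are excluded
#' wherever they sit, regardless of allele; set `match_alleles = TRUE` to
#' additionally require the catalog's ref>alt pair to equal one of the
#' call's observed substitutions (forward-strand reading).
#'
#' @param calls A site-call table.
#' @param snvs An [read_snv_catalog()] catalog.
#' @param match_alleles Require allele agreement, not just position
#'   (default `FALSE`).
#' @return The surviving calls, in their original order.
#' @export
exclude_snv_positions <- function(calls, snvs, match_alleles = FALSE) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L || nrow(snvs) == 0L) return(calls[])
  key <- paste(calls$chrom, calls$position)
  hit <- key %in% paste(snvs$chrom, snvs$pos)
  if (match_alleles && any(hit)) {
    idx <- match(key, paste(snvs$chrom, snvs$pos))
    sub_snv <- paste0(snvs$ref[idx], snvs$alt[idx])
    # a call only falls if the catalog allele is among its observed
    # substitutions on the forward strand
    fwd <- forward_substitutions(calls)
    hit <- hit & mapply(function(s, subs) !is.na(s) && s %in% subs,
                        sub_snv, fwd)
  }
  calls[!hit][]
}

## Observed substitutions on the forward reference strand, undoing the
## complement applied by assign_strand() for minus-strand calls.
forward_substitutions <- function(calls) {
  subs <- strsplit(calls$substitutions, ",", fixed = TRUE)
  minus <- calls$strand == "-"
  subs[minus] <- lapply(subs[minus], chartr, old = "ACGT", new = "TGCA")
  subs
}

#' Restrict calls to A-to-I candidates in protein-coding regions
#'
#' Keeps strand-resolved A>G calls whose position lies inside a coding
#' interval, and attaches the overlapping gene's name.
#'
#' @param calls A site-call table with strand assigned
#'   (see [assign_strand()]).
#' @param annotation Coding annotation from [read_annotation()].
#' @return The surviving calls with a `gene` column.
#' @export
restrict_coding_a_to_i <- function(calls, annotation) {
  calls <- copy(as.data.table(calls))
  if (nrow(calls) == 0L) {
    if (!"gene" %in% names(calls)) calls[, gene := character()]
    return(calls[])
  }
  hits <- annotation_hits(annotation, calls$chrom, calls$position)
  in_coding <- seq_len(nrow(calls)) %in% hits$idx
  if (!"gene" %in% names(calls)) calls[, gene := NA_character_]
  if (nrow(hits)) {
    g <- hits[, .(gene = sort(gene)[1L]), by = idx]
    fill <- g$idx[is.na(calls$gene[g$idx])]
    if (length(fill))
      calls$gene[fill] <- g$gene[match(fill, g$idx)]
  }
  calls[in_coding & is_a_to_i == TRUE][]
}

#' Split coding A-to-I calls by known-editing-site membership
#'
#' Partitions the (already filtered) calls into the branch matched to the
#' known-editing-site catalog — used for per-site differential testing —
#' and keeps the full set for the burden analysis. A call matches when the
#' catalog holds its (chromosome, position) with substitution `AG` (the
#' call's strand-resolved substitution list must contain `AG`) and a
#' strand agreeing with the call's assigned strand; a strand conflict
#' leaves the call unmatched with a warning.
#'
#' @param calls Coding A-to-I site-call table.
#' @param known A [read_known_sites()] catalog.
#' @return A `filtered_sites` object: list with `coding_a_to_i` (all input
#'   calls) and `known_matched` (the matched subset).
#' @export
split_by_known <- function(calls, known) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L || nrow(known) == 0L) {
    res <- list(coding_a_to_i = calls[], known_matched = calls[0][])
    class(res) <- "filtered_sites"
    return(res)
  }
  idx <- match(paste(calls$chrom, calls$position),
               paste(known$chrom, known$position))
  has_ag <- vapply(strsplit(calls$substitutions, ",", fixed = TRUE),
                   function(s) "AG" %in% s, TRUE)
  matched <- !is.na(idx) & known$substitution[idx] == "AG" & has_ag
  conflict <- matched & known$strand[idx] != calls$strand
  if (any(conflict)) {
    warning(sum(conflict), " known-site match(es) discarded for strand ",
            "conflict with the assigned gene strand", call. = FALSE)
    matched <- matched & !conflict
  }
  res <- list(coding_a_to_i = calls[], known_matched = calls[matched][])
  class(res) <- "filtered_sites"
  res
}

#' @export
print.filtered_sites <- function(x, ...) {
  cat("Filtered site sets: ", nrow(x$coding_a_to_i),
      " coding A-to-I calls, ", nrow(x$known_matched),
      " matched to known editing sites\n", sep = "")
  invisible(x)
}
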