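## Readers/writers for the standard formats the pipeline touches, plus the
## catalog containers shared by the filtering stages. All user-facing
## coordinates are 1-based; interval logic lives on GenomicRanges, with
## rtracklayer normalizing BED (0-based half-open) and GTF (1-based
## inclusive) on import.

VALID_SUBSTITUTIONS <- c("AC", "AG", "AT", "CA", "CG", "CT",
                         "GA", "GC", "GT", "TA", "TC", "TG")

#' Read a genomic SNV catalog from VCF
#'
#' Loads positions of known single-nucleotide variants (a gnomAD-style
#' catalog) used to exclude genomic polymorphisms from candidate editing
#' sites. Multi-allelic records yield one positional entry; duplicate
#' (chromosome, position) records collapse to one.
#'
#' @param path Path to a VCF file (plain or gzip/bgzip compressed).
#' @return An object of class `snv_catalog`: a `data.table` with columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, one row per unique position.
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'   "chr1\t100\t.\tA\tG\t.\tPASS\t."), vcf)
#' read_snv_catalog(vcf)
#' @export
read_snv_catalog <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(new_snv_catalog(data.table(chrom = character(), pos = integer(),
                                      ref = character(), alt = character())))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop("malformed VCF record ", bad[1L], " in '", path,
         "': non-positive or non-numeric POS", call. = FALSE)
  dt <- data.table(chrom = as.character(fix[, "CHROM"]), pos = pos,
                   ref = as.character(fix[, "REF"]),
                   alt = as.character(fix[, "ALT"]))
  dt <- unique(dt, by = c("chrom", "pos"))
  new_snv_catalog(dt)
}

new_snv_catalog <- function(dt) {
  setkeyv(dt, c("chrom", "pos"))
  setattr(dt, "class", c("snv_catalog", class(dt)))
  dt[]
}

#' @export
print.snv_catalog <- function(x, ...) {
  cat("SNV catalog:", nrow(x), "positions on",
      length(unique(x$chrom)), "sequences\n")
  if (nrow(x)) print(as.data.table(head(x, 5L)))
  invisible(x)
}

#' Read a known-editing-site catalog
#'
#' Loads a REDIportal-style whitelist of known editing positions from a
#' tab-separated file with columns `chrom`, `position`, `strand`,
#' `substitution` (header optional). Later duplicate rows for the same
#' position overwrite earlier ones, with a warning.
#'
#' @param path Path to the TSV file (optionally gzip compressed).
#' @return An object of class `known_sites`: a keyed `data.table` with
#'   columns `chrom`, `position`, `strand` (`+`/`-`) and `substitution`
#'   (two-letter code such as `"AG"`, read 5'->3' on the annotated strand).
#' @export
read_known_sites <- function(path) {
  if (file.exists(path) && file.size(path) == 0L) {
    dt <- data.table(chrom = character(), position = integer(),
                     strand = character(), substitution = character())
    return(new_known_sites(dt))
  }
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              strip.white = TRUE, fill = TRUE)
  if (nrow(dt) && ncol(dt) < 4L)
    stop("known-site catalog needs 4 columns (chrom, position, strand, ",
         "substitution); got ", ncol(dt), call. = FALSE)
  if (nrow(dt) == 0L) {
    dt <- data.table(chrom = character(), position = integer(),
                     strand = character(), substitution = character())
    return(new_known_sites(dt))
  }
  dt <- dt[, 1:4]
  setnames(dt, c("chrom", "position", "strand", "substitution"))
  # tolerate a header line
  if (is.na(suppressWarnings(as.integer(dt$position[1L]))))
    dt <- dt[-1L]
  dt[, strand := chartr("−", "-", strand)]  # unicode minus
  dt[, position := as.integer(position)]
  if (anyNA(dt$position) || any(dt$position < 1L))
    stop("known-site catalog '", path, "': non-numeric or non-positive ",
         "position", call. = FALSE)
  bad <- !dt$strand %in% c("+", "-")
  if (any(bad))
    stop("known-site catalog '", path, "': invalid strand token '",
         dt$strand[which(bad)[1L]], "'", call. = FALSE)
  dt[, substitution := toupper(substitution)]
  bad <- !dt$substitution %in% VALID_SUBSTITUTIONS
  if (any(bad))
    stop("known-site catalog '", path, "': invalid substitution token '",
         dt$substitution[which(bad)[1L]], "'", call. = FALSE)
  dup <- duplicated(dt, by = c("chrom", "position"), fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate position(s) in known-site catalog; ",
            "later rows overwrite earlier ones", call. = FALSE)
    dt <- dt[!dup]
  }
  new_known_sites(dt)
}

new_known_sites <- function(dt) {
  setkeyv(dt, c("chrom", "position"))
  setattr(dt, "class", c("known_sites", class(dt)))
  dt[]
}

#' @export
print.known_sites <- function(x, ...) {
  cat("Known editing sites:", nrow(x), "positions\n")
  if (nrow(x)) print(as.data.table(head(x, 5L)))
  invisible(x)
}

#' Write a known-editing-site catalog
#'
#' Inverse of [read_known_sites()]; round-trips exactly.
#'
#' @param sites A `known_sites` object (or data.frame with the same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_known_sites <- function(sites, path) {
  dt <- as.data.table(sites)[, .(chrom, position, strand, substitution)]
  fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read coding annotation from GTF/GFF or BED
#'
#' Loads protein-coding regions used both for the coding-region restriction
#' and for gene-strand assignment. GTF/GFF input keeps `CDS` features
#' (falling back to `exon` if no CDS is present) and takes the gene name
#' from the `gene_name` attribute (falling back to `gene_id`). BED input
#' must be at least BED6 (a strand per interval).
#'
#' @param path Path to a `.gtf`, `.gff`/`.gff3` or `.bed` file, optionally
#'   `.gz` compressed.
#' @return A [GenomicRanges::GRanges] of coding intervals (1-based closed)
#'   with a `gene` metadata column and a strand per interval.
#' @export
read_annotation <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("gtf", "gff", "gff3", "gff2")) {
    gr <- rtracklayer::import(path, format = if (ext == "gtf") "gtf" else "gff")
    type <- as.character(gr$type)
    keep <- if (any(type == "CDS")) type == "CDS" else type == "exon"
    gr <- gr[keep]
    gene <- if (!is.null(gr$gene_name)) as.character(gr$gene_name)
            else as.character(gr$gene_id)
    if (is.null(gene)) gene <- rep(NA_character_, length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene = gene)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (any(as.character(strand(gr)) == "*"))
      stop("BED annotation '", path, "' has strandless intervals; ",
           "BED6 with strand required", call. = FALSE)
    gene <- if (!is.null(gr$name)) as.character(gr$name)
            else rep(NA_character_, length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene = gene)
  } else {
    stop("unknown annotation format '.", ext, "' (expected gtf/gff/bed)",
         call. = FALSE)
  }
  gr
}

## Overlap of 1-based points against the annotation. Returns a data.table
## (idx, gene, strand), one row per (point, overlapping interval) pair.
annotation_hits <- function(annotation, chrom, position) {
  if (length(chrom) == 0L)
    return(data.table(idx = integer(), gene = character(),
                      strand = character()))
  q <- GRanges(chrom, IRanges(position, position))
  hits <- findOverlaps(q, annotation, ignore.strand = TRUE)
  data.table(
    idx = queryHits(hits),
    gene = as.character(annotation$gene[subjectHits(hits)]),
    strand = as.character(strand(annotation)[subjectHits(hits)])
  )
}

#' Write a differential-editing site table
#'
#' Writes one row per tested site with edited-sample counts formatted
#' `"k/n"` and p-values in scientific notation with 3 significant digits.
#' Rows are sorted by adjusted p ascending, ties broken by raw p, then by
#' (chromosome, position).
#'
#' @param records An [differential_table()] result (`edit_diff`) or a
#'   data.frame with columns `gene`, `chrom`, `position`, `k_control`,
#'   `n_control`, `k_case`, `n_case`, `p_fisher`, `p_adjusted`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(records, path) {
  dt <- as.data.table(as.data.frame(records))
  need <- c("gene", "chrom", "position", "k_control", "n_control",
            "k_case", "n_case", "p_fisher", "p_adjusted")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("site table records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  setorderv(dt, c("p_adjusted", "p_fisher", "chrom", "position"))
  out <- data.table(
    gene = dt$gene, chrom = dt$chrom, position = dt$position,
    edited_control = sprintf("%d/%d", dt$k_control, dt$n_control),
    edited_case = sprintf("%d/%d", dt$k_case, dt$n_case),
    p_fisher = formatC(dt$p_fisher, format = "e", digits = 2),
    p_adjusted = formatC(dt$p_adjusted, format = "e", digits = 2)
  )
  fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a differential-editing site table
#'
#' Inverse of [write_site_table()] at the file's printed precision: counts
#' are split back into `k`/`n` pairs and p-values parsed from scientific
#' notation.
#'
#' @param path Path written by [write_site_table()].
#' @return A `data.table` with the [write_site_table()] input columns.
#' @export
read_site_table <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "gene"))
  if (nrow(dt) == 0L)
    return(data.table(gene = character(), chrom = character(),
                      position = integer(), k_control = integer(),
                      n_control = integer(), k_case = integer(),
                      n_case = integer(), p_fisher = numeric(),
                      p_adjusted = numeric()))
  kc <- strsplit(dt$edited_control, "/", fixed = TRUE)
  kp <- strsplit(dt$edited_case, "/", fixed = TRUE)
  data.table(
    gene = as.character(dt$gene), chrom = as.character(dt$chrom),
    position = as.integer(dt$position),
    k_control = as.integer(vapply(kc, `[`, "", 1L)),
    n_control = as.integer(vapply(kc, `[`, "", 2L)),
    k_case = as.integer(vapply(kp, `[`, "", 1L)),
    n_case = as.integer(vapply(kp, `[`, "", 2L)),
    p_fisher = as.numeric(dt$p_fisher),
    p_adjusted = as.numeric(dt$p_adjusted)
  )
}

#' Write / read a per-sample candidate-site table
#'
#' The per-sample caller output: chromosome, position, strand, reference
#' base, base distribution, coverage, mean base quality, observed
#' substitutions (comma-separated, most supported first) and the variation
#' frequency of the principal substitution.
#'
#' @param calls A site-call `data.table` from [call_sites()].
#' @param path Output path.
#' @return `path` ([write_site_calls()]) or the calls table
#'   ([read_site_calls()]).
#' @export
write_site_calls <- function(calls, path) {
  dt <- as.data.table(calls)
  cols <- c("chrom", "position", "strand", "ref", "A", "C", "G", "T",
            "coverage", "mean_quality", "substitutions", "frequency",
            "is_a_to_i")
  if ("gene" %in% names(dt)) cols <- c(cols, "gene")
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' @rdname write_site_calls
#' @export
read_site_calls <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("chrom", "strand", "ref",
                                              "substitutions")))
  dt[, position := as.integer(position)]
  dt[]
}
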