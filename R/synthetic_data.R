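## Seeded synthetic cohorts: a small reference with coding genes on both
## strands, planted editing sites (per-sample Bernoulli prevalence, per-read
## editing rate), het/hom SNVs that mimic editing, uniform sequencing error,
## and properly paired 100M/100M alignments emitted as SAM and converted to
## sorted, indexed BAM. Everything is deterministic given the seed.

#' Default panel of planted editing sites
#'
#' Five differentially edited sites (prevalence 0.9 in controls vs 0.2 in
#' cases, per-read editing rate 0.8) over forty null sites (prevalence 0.5
#' in both groups, rate 0.5).
#'
#' @param n_differential,n_null Numbers of differential and null sites.
#' @param pi_control_diff,pi_case_diff Group prevalences at differential
#'   sites.
#' @param pi_null Shared prevalence at null sites.
#' @param phi_diff,phi_null Per-read editing rates.
#' @return data.frame with columns `pi_control`, `pi_case`, `phi`.
#' @export
site_panel <- function(n_differential = 5L, n_null = 40L,
                       pi_control_diff = 0.9, pi_case_diff = 0.2,
                       pi_null = 0.5, phi_diff = 0.8, phi_null = 0.5) {
  rbind(
    if (n_differential > 0L)
      data.frame(pi_control = pi_control_diff, pi_case = pi_case_diff,
                 phi = phi_diff)[rep(1L, n_differential), , drop = FALSE],
    if (n_null > 0L)
      data.frame(pi_control = pi_null, pi_case = pi_null,
                 phi = phi_null)[rep(1L, n_null), , drop = FALSE]
  )
}

#' Configuration of a synthetic editing cohort
#'
#' Truth parameters for [simulate_reference()], [simulate_sample()],
#' [simulate_cohort()], [simulate_profiles()] and [run_end_to_end()].
#' Cohort sizes default to 44 control and 29 case samples and reads to
#' 2 x 100 nt proper pairs, mirroring a typical postmortem brain RNA-Seq
#' cohort; tests and examples use smaller cohorts.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of it.
#' @param n_control,n_case Cohort sizes.
#' @param sites data.frame of planted sites (`pi_control`, `pi_case`,
#'   `phi`): per-group probability that a sample is edited at the site,
#'   and the per-read editing rate given edited. Default [site_panel()].
#' @param known_fraction Fraction of planted sites written to the
#'   known-editing-site catalog (taken from the head of `sites`, so
#'   differential sites are catalogued first). Default 1.
#' @param n_snv_het,n_snv_hom Numbers of heterozygous / homozygous planted
#'   SNVs; their alleles mimic A-to-I editing so that only the SNV-catalog
#'   filter can remove them.
#' @param n_genes,gene_length,intergenic,exons_per_gene,intron_length
#'   Layout of the synthetic genome: genes alternate strand, each with
#'   `exons_per_gene` coding exons totalling `gene_length` bases.
#' @param chrom_name Name of the single synthetic chromosome.
#' @param read_length,insert_size Read geometry (bases); mates never
#'   overlap when `insert_size >= 2 * read_length`.
#' @param base_quality Constant phred base quality written to reads.
#' @param mean_coverage Target mean per-base coverage.
#' @param coverage_jitter Per-sample uniform multiplier range on coverage,
#'   creating variable library sizes.
#' @param error_rate Per-base probability of a uniform wrong base.
#' @param library_size_range Mapped-read-count range used by the
#'   statistical-layer simulator [simulate_profiles()] (read-level
#'   simulation derives library sizes from coverage instead).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(seed = 1L,
                              n_control = 44L, n_case = 29L,
                              sites = site_panel(),
                              known_fraction = 1,
                              n_snv_het = 2L, n_snv_hom = 2L,
                              n_genes = 6L, gene_length = 600L,
                              intergenic = 200L, exons_per_gene = 1L,
                              intron_length = 100L,
                              chrom_name = "chr1",
                              read_length = 100L, insert_size = 250L,
                              base_quality = 35L,
                              mean_coverage = 50,
                              coverage_jitter = c(0.7, 1.3),
                              error_rate = 0.001,
                              library_size_range = c(2e7, 6e7)) {
  sites <- as.data.frame(sites)
  stopifnot(
    is.numeric(seed), length(seed) == 1L, !is.na(seed),
    n_control >= 1L, n_case >= 1L,
    nrow(sites) >= 1L,
    all(c("pi_control", "pi_case", "phi") %in% names(sites)),
    all(sites$pi_control >= 0 & sites$pi_control <= 1),
    all(sites$pi_case >= 0 & sites$pi_case <= 1),
    all(sites$phi > 0 & sites$phi <= 1),
    known_fraction >= 0, known_fraction <= 1,
    n_snv_het >= 0L, n_snv_hom >= 0L,
    n_genes >= 1L, gene_length >= exons_per_gene,
    exons_per_gene >= 1L, intron_length >= 1L, intergenic >= 0L,
    read_length >= 20L, insert_size >= read_length,
    error_rate >= 0, error_rate < 1,
    mean_coverage > 0,
    length(coverage_jitter) == 2L, all(coverage_jitter > 0),
    length(library_size_range) == 2L, all(library_size_range > 0)
  )
  structure(list(
    seed = as.integer(seed), n_control = as.integer(n_control),
    n_case = as.integer(n_case), sites = sites,
    known_fraction = known_fraction,
    n_snv_het = as.integer(n_snv_het), n_snv_hom = as.integer(n_snv_hom),
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    intergenic = as.integer(intergenic),
    exons_per_gene = as.integer(exons_per_gene),
    intron_length = as.integer(intron_length),
    chrom_name = chrom_name,
    read_length = as.integer(read_length),
    insert_size = as.integer(insert_size),
    base_quality = as.integer(base_quality),
    mean_coverage = mean_coverage,
    coverage_jitter = coverage_jitter,
    error_rate = error_rate,
    library_size_range = library_size_range
  ), class = "simulation_config")
}

## Independent RNG substreams so that reference and every sample are
## deterministic regardless of how many draws other stages consume.
derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 1000003) * 1009 + k) %% 2147483629
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate the reference side of a cohort
#'
#' Writes a FASTA genome (+ .fai), a GTF with gene/exon/CDS features, a
#' known-editing-site TSV and an SNV VCF into `dir`, placing every
#' configured editing site at an adenosine (on its gene's strand) inside a
#' coding exon. Planted SNVs also mimic A-to-I substitutions so they are
#' only removable via the VCF catalog. Deterministic given the config
#' seed.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return A `sim_reference` list: file paths, the genome
#'   (`DNAStringSet`), the coding annotation (`GRanges`), the site truth
#'   table and the planted-SNV table.
#' @export
simulate_reference <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(derive_seed(config$seed, 0), {
    exon_len <- ceiling(config$gene_length / config$exons_per_gene)
    gene_span <- config$exons_per_gene * exon_len +
      (config$exons_per_gene - 1L) * config$intron_length
    L <- config$n_genes * (gene_span + config$intergenic) +
      config$intergenic
    genome_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    exon_list <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      gs <- config$intergenic + (i - 1L) * (gene_span + config$intergenic) + 1L
      starts <- gs + (seq_len(config$exons_per_gene) - 1L) *
        (exon_len + config$intron_length)
      exon_list[[i]] <- data.table(
        gene = sprintf("gene%02d", i),
        strand = if (i %% 2L == 1L) "+" else "-",
        start = starts, end = starts + exon_len - 1L
      )
    }
    exons <- rbindlist(exon_list)
    coding_pos <- unlist(lapply(seq_len(nrow(exons)),
                                function(i) exons$start[i]:exons$end[i]))
    coding_gene <- rep(exons$gene, exons$end - exons$start + 1L)
    coding_strand <- rep(exons$strand, exons$end - exons$start + 1L)

    n_sites <- nrow(config$sites)
    n_snv <- config$n_snv_het + config$n_snv_hom
    if (n_sites + n_snv > length(coding_pos))
      stop("not enough coding positions for the configured sites and SNVs",
           call. = FALSE)
    picked <- sample(length(coding_pos), n_sites + n_snv)
    site_idx <- picked[seq_len(n_sites)]
    snv_idx <- picked[n_sites + seq_len(n_snv)]

    # editing sites sit at A on the gene strand: A on '+', T on '-'
    sites <- data.table(
      site_id = sprintf("site%03d", seq_len(n_sites)),
      chrom = config$chrom_name,
      position = coding_pos[site_idx],
      gene = coding_gene[site_idx],
      strand = coding_strand[site_idx],
      pi_control = config$sites$pi_control,
      pi_case = config$sites$pi_case,
      phi = config$sites$phi
    )
    sites[, differential := pi_control != pi_case]
    n_known <- round(config$known_fraction * n_sites)
    sites[, known := seq_len(n_sites) <= n_known]
    genome_chars[sites$position] <- ifelse(sites$strand == "+", "A", "T")

    snvs <- if (n_snv > 0L) {
      s <- data.table(
        chrom = config$chrom_name,
        position = coding_pos[snv_idx],
        strand = coding_strand[snv_idx],
        genotype = rep(c("het", "hom"),
                       c(config$n_snv_het, config$n_snv_hom))
      )
      s[, ref := ifelse(strand == "+", "A", "T")]
      s[, alt := ifelse(strand == "+", "G", "C")]
      genome_chars[s$position] <- s$ref
      s
    } else {
      data.table(chrom = character(), position = integer(),
                 strand = character(), genotype = character(),
                 ref = character(), alt = character())
    }
    setorder(sites, position)
    setorder(snvs, position)

    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- config$chrom_name
    fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fasta)
    Rsamtools::indexFa(fasta)

    gtf <- file.path(dir, "genes.gtf")
    feats <- rbindlist(list(
      exons[, .(start = min(start), end = max(end), type = "gene"),
            by = .(gene, strand)],
      copy(exons)[, type := "exon"],
      copy(exons)[, type := "CDS"]
    ), use.names = TRUE, fill = TRUE)
    gr <- GRanges(config$chrom_name,
                  IRanges(feats$start, feats$end), strand = feats$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "editdiff_sim", type = feats$type,
      phase = ifelse(feats$type == "CDS", 0L, NA_integer_),
      gene_id = feats$gene, gene_name = feats$gene,
      transcript_id = paste0(feats$gene, ".t1"))
    rtracklayer::export(gr, gtf, format = "gtf")

    known_tsv <- file.path(dir, "known_sites.tsv")
    write_known_sites(
      sites[known == TRUE,
            .(chrom, position, strand, substitution = "AG")],
      known_tsv)

    vcf <- file.path(dir, "snvs.vcf")
    writeLines(c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s,length=%d>", config$chrom_name, L),
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            sep = "\t"),
      if (nrow(snvs))
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                snvs$chrom, snvs$position, snvs$ref, snvs$alt)
    ), vcf)

    truth_tsv <- file.path(dir, "truth_sites.tsv")
    fwrite(sites, truth_tsv, sep = "\t")

    structure(list(
      config = config, dir = dir, genome_length = L,
      fasta = fasta, gtf = gtf, known_tsv = known_tsv, vcf = vcf,
      truth_tsv = truth_tsv,
      genome = genome, exons = exons[], sites = sites[], snvs = snvs[]
    ), class = "sim_reference")
  })
}

#' Simulate one sample's aligned reads
#'
#' Draws the sample's edited status at every planted site
#' (`Bernoulli(pi_group)`), then emits properly paired, uniquely mapped
#' 100M/100M reads over the genome: reads over edited sites carry the
#' edited base with probability `phi`; heterozygous SNVs put the alternate
#' allele on each fragment with probability 0.5 (homozygous always);
#' every base is replaced by a uniform wrong base with probability
#' `error_rate`. The SAM is converted to a coordinate-sorted, indexed BAM.
#'
#' @param reference A [simulate_reference()] result.
#' @param group `"control"` or `"case"`.
#' @param sample_index Global 1-based sample index (drives the RNG
#'   substream).
#' @param dir Output directory (default: the reference directory).
#' @return List: `sample_id`, `group`, `sam`, `bam`, `library_size`
#'   (mapped reads) and `truth` (per-site edited indicator).
#' @export
simulate_sample <- function(reference, group, sample_index,
                            dir = reference$dir) {
  stopifnot(inherits(reference, "sim_reference"),
            group %in% c("control", "case"))
  cfg <- reference$config
  with_seed(derive_seed(cfg$seed, sample_index), {
    sites <- reference$sites
    pi <- if (group == "control") sites$pi_control else sites$pi_case
    edited <- rbinom(nrow(sites), 1L, pi) == 1L

    L <- reference$genome_length
    rl <- cfg$read_length
    jit <- runif(1L, cfg$coverage_jitter[1L], cfg$coverage_jitter[2L])
    n_pairs <- max(1L, round(L * cfg$mean_coverage * jit / (2 * rl)))
    frag <- sample.int(L - cfg$insert_size + 1L, n_pairs, replace = TRUE)
    pos1 <- frag
    pos2 <- frag + cfg$insert_size - rl
    starts <- c(pos1, pos2)                  # read i, i+n_pairs = one pair
    genome_str <- as.character(reference$genome[[1L]])
    seqs <- substring(genome_str, starts, starts + rl - 1L)
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = rl)

    put <- function(lin, value) if (length(lin)) chars[lin] <<- value

    # SNV alleles: one draw per fragment, both mates carry it
    if (nrow(reference$snvs)) {
      for (i in seq_len(nrow(reference$snvs))) {
        sv <- reference$snvs[i]
        carry <- if (sv$genotype == "hom") rep(TRUE, n_pairs)
                 else rbinom(n_pairs, 1L, 0.5) == 1L
        carry2 <- rep(carry, 2L)
        off <- sv$position - starts + 1L
        hit <- which(off >= 1L & off <= rl & carry2)
        put((hit - 1L) * rl + off[hit], sv$alt)
      }
    }
    # editing: per read, probability phi at edited sites
    ed_idx <- which(edited)
    for (i in ed_idx) {
      off <- sites$position[i] - starts + 1L
      hit <- which(off >= 1L & off <= rl)
      if (length(hit)) {
        carry <- rbinom(length(hit), 1L, sites$phi[i]) == 1L
        hit <- hit[carry]
        put((hit - 1L) * rl + off[hit],
            if (sites$strand[i] == "+") "G" else "C")
      }
    }
    # uniform sequencing error
    if (cfg$error_rate > 0) {
      nbase <- length(chars)
      err <- which(runif(nbase) < cfg$error_rate)
      if (length(err)) {
        alt3 <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))
        cur <- chars[err]
        pick <- sample.int(3L, length(err), replace = TRUE)
        chars[err] <- mapply(function(b, k) alt3[[b]][k], cur, pick,
                             USE.NAMES = FALSE)
      }
    }

    seqs <- apply(chars, 2L, paste, collapse = "")
    qual <- strrep(rawToChar(as.raw(cfg$base_quality + 33L)), rl)
    sample_id <- sprintf("%s%02d", if (group == "control") "ctrl" else "case",
                         sample_index)
    qname <- sprintf("%s.frag%06d", sample_id, seq_len(n_pairs))
    cig <- paste0(rl, "M")
    rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s\tNH:i:1",
                    qname, cfg$chrom_name, pos1, cig, pos2,
                    cfg$insert_size, seqs[seq_len(n_pairs)], qual)
    rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s\tNH:i:1",
                    qname, cfg$chrom_name, pos2, cig, pos1,
                    -cfg$insert_size, seqs[n_pairs + seq_len(n_pairs)], qual)
    sam <- file.path(dir, paste0(sample_id, ".sam"))
    writeLines(c(
      "@HD\tVN:1.6",
      sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom_name, L),
      sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id),
      rbind(rec1, rec2)  # interleave mates
    ), sam)
    bam <- suppressMessages(Rsamtools::asBam(
      sam, file.path(dir, sample_id), overwrite = TRUE,
      indexDestination = TRUE))

    list(sample_id = sample_id, group = group, sam = sam, bam = bam,
         library_size = 2L * n_pairs,
         truth = data.table(sample_id = sample_id,
                            site_id = sites$site_id,
                            chrom = sites$chrom, position = sites$position,
                            edited = edited))
  })
}

#' Simulate a complete cohort (reference plus all samples)
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return A `sim_cohort` list: `reference`, `samples` (list of
#'   [simulate_sample()] results, controls first) and the stacked
#'   per-sample `truth` table.
#' @export
simulate_cohort <- function(config, dir) {
  reference <- simulate_reference(config, dir)
  groups <- rep(c("control", "case"), c(config$n_control, config$n_case))
  samples <- lapply(seq_along(groups), function(i)
    simulate_sample(reference, groups[i], i))
  structure(list(
    reference = reference, samples = samples,
    truth = rbindlist(lapply(samples, `[[`, "truth"))
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cfg <- x$reference$config
  cat("Synthetic cohort: ", cfg$n_control, " control + ", cfg$n_case,
      " case samples, ", nrow(x$reference$sites), " planted sites (",
      sum(x$reference$sites$differential), " differential), genome ",
      x$reference$genome_length, " bp\n", sep = "")
  invisible(x)
}

#' Statistical-layer cohort simulation (no reads)
#'
#' Draws each sample's edited-site set directly from the per-site
#' Bernoulli prevalences — the same truth process as the read-level
#' simulator — thinned by the per-sample detection probability
#' `1 - (1 - phi)^mean_coverage` (essentially 1 at default coverage), and
#' draws library sizes uniformly from `library_size_range`. Used for
#' replicate-heavy property checks (e.g. false-discovery calibration)
#' where emitting reads adds nothing.
#'
#' @param config A [simulation_config()].
#' @return A [sample_profiles()] cohort with attributes `truth` (site
#'   table with prevalences and differential flags) and `config`.
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 500000), {
    n_sites <- nrow(config$sites)
    site_pos <- 100L * seq_len(n_sites)
    truth <- data.table(
      site_id = sprintf("site%03d", seq_len(n_sites)),
      chrom = config$chrom_name, position = site_pos,
      pi_control = config$sites$pi_control,
      pi_case = config$sites$pi_case,
      phi = config$sites$phi
    )
    truth[, differential := pi_control != pi_case]
    pdet <- 1 - (1 - truth$phi)^config$mean_coverage

    groups <- rep(c("control", "case"), c(config$n_control, config$n_case))
    ids <- sprintf("%s%02d", ifelse(groups == "control", "ctrl", "case"),
                   seq_along(groups))
    edited <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      pi <- if (groups[i] == "control") truth$pi_control else truth$pi_case
      hit <- rbinom(n_sites, 1L, pi * pdet) == 1L
      edited[[i]] <- if (any(hit))
        data.table(sample_id = ids[i], chrom = config$chrom_name,
                   position = site_pos[hit])
      else
        data.table(sample_id = character(), chrom = character(),
                   position = integer())
    }
    samples <- data.table(
      sample_id = ids, group = groups,
      library_size = runif(length(groups), config$library_size_range[1L],
                           config$library_size_range[2L])
    )
    prof <- sample_profiles(samples, rbindlist(edited))
    attr(prof, "truth") <- truth[]
    attr(prof, "config") <- config
    prof
  })
}

#' Run the full pipeline on a simulated cohort and score recovery
#'
#' Simulates reference and reads, then runs, per sample, pileup ->
#' variant calling -> strand assignment -> coding A-to-I restriction ->
#' SNV exclusion -> known-site split, builds the differential table on
#' the known-matched branch (family size = number of tested sites) and
#' the editing-burden comparison on the all-sites branch, and compares
#' the significant calls with the planted truth.
#'
#' @param config A [simulation_config()].
#' @param dir Working directory for the simulated files (default: a
#'   temporary directory).
#' @param alpha Adjusted-p significance level for recovery (default 0.05).
#' @param filter A [filter_config()].
#' @return An `edit_recovery` object: `diff` ([differential_table()]
#'   result), `burden` ([edit_burden()] result), `recovery` (per planted
#'   site: tested / significant vs truth) and `summary` counts.
#' @export
run_end_to_end <- function(config, dir = tempfile("editdiff_sim"),
                           alpha = 0.05, filter = filter_config()) {
  cohort <- simulate_cohort(config, dir)
  ref <- cohort$reference
  snvs <- read_snv_catalog(ref$vcf)
  known <- read_known_sites(ref$known_tsv)
  anno <- read_annotation(ref$gtf)
  genome <- load_reference(ref$fasta)

  matched_tables <- list(); all_tables <- list()
  groups <- character(); libsizes <- numeric()
  for (s in cohort$samples) {
    pile <- accumulate_pileup(s$bam, config = filter)
    calls <- call_sites(pile, genome, config = filter)
    calls <- assign_strand(calls, anno)
    calls <- restrict_coding_a_to_i(calls, anno)
    calls <- exclude_snv_positions(calls, snvs)
    split <- split_by_known(calls, known)
    matched_tables[[s$sample_id]] <- split$known_matched
    all_tables[[s$sample_id]] <- split$coding_a_to_i
    groups[s$sample_id] <- s$group
    libsizes[s$sample_id] <- s$library_size
  }
  prof_matched <- profiles_from_calls(matched_tables, groups, libsizes)
  prof_all <- profiles_from_calls(all_tables, groups, libsizes)

  tested <- unique(rbindlist(lapply(matched_tables, function(ct)
    as.data.table(ct)[, .(chrom, position, gene)])),
    by = c("chrom", "position"))
  if (nrow(tested) == 0L)
    stop("no known-matched sites detected in any sample", call. = FALSE)
  diff <- differential_table(prof_matched, tested, alpha = alpha)
  burden <- edit_burden(prof_all)

  recovery <- merge(
    ref$sites[, .(site_id, chrom, position, gene, differential, known)],
    diff$table[, .(chrom, position, p_fisher, p_adjusted)],
    by = c("chrom", "position"), all.x = TRUE)
  recovery[, tested := !is.na(p_adjusted)]
  recovery[, significant := tested & p_adjusted <= alpha]
  setorder(recovery, position)

  summary <- list(
    n_true = sum(recovery$differential),
    n_true_recovered = sum(recovery$differential & recovery$significant),
    n_null_tested = sum(!recovery$differential & recovery$tested),
    n_null_significant = sum(!recovery$differential & recovery$significant),
    alpha = alpha
  )
  structure(list(diff = diff, burden = burden, recovery = recovery[],
                 summary = summary, dir = dir),
            class = "edit_recovery")
}

#' @export
print.edit_recovery <- function(x, ...) {
  s <- x$summary
  cat("End-to-end recovery at adjusted p <= ", s$alpha, ":\n", sep = "")
  cat("  true differential sites recovered: ", s$n_true_recovered, " / ",
      s$n_true, "\n", sep = "")
  cat("  null sites tested / flagged:       ", s$n_null_tested, " / ",
      s$n_null_significant, "\n", sep = "")
  cat(sprintf("  burden rank-sum p (normalized):    %.4g\n",
              x$burden$p_normalized))
  invisible(x)
}
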