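# Independent reference implementations used to validate the package's
# computations. Each is deliberately naive (loops, enumeration) and shares
# no code path with the implementation it checks.

# Per-read, per-position pileup: walks every read's CIGAR character by
# character and applies the filters literally.
oracle_pileup <- function(records, min_bq = 30L, min_mapq = 60L,
                          exclude_dup = TRUE, exclude_multi = TRUE,
                          require_proper = TRUE) {
  # records: data.frame qname, flag, chrom, pos, mapq, cigar, seq, qual
  # (qual = integer list column), nh (NA if absent)
  acc <- list()  # key "chrom:pos" -> list of (qname, first, base, qual)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    flag <- r$flag
    if (bitwAnd(flag, 4L) > 0L) next                       # unmapped
    if (exclude_dup && bitwAnd(flag, 1024L) > 0L) next     # duplicate
    if (exclude_multi && bitwAnd(flag, 256L) > 0L) next    # secondary
    if (exclude_multi && bitwAnd(flag, 2048L) > 0L) next   # supplementary
    if (exclude_multi && !is.na(r$nh) && r$nh > 1L) next
    if (require_proper && bitwAnd(flag, 2L) == 0L) next
    if (r$mapq < min_mapq) next
    ops <- regmatches(r$cigar, gregexpr("[0-9]+[MIDNSHP=X]", r$cigar))[[1]]
    gpos <- r$pos; qpos <- 1L
    sq <- strsplit(r$seq, "")[[1]]
    qq <- r$qual[[1]]
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      o <- sub("[0-9]+", "", op)
      if (o %in% c("M", "=", "X")) {
        for (k in seq_len(n)) {
          key <- paste0(r$chrom, ":", gpos + k - 1L)
          acc[[key]] <- c(acc[[key]], list(list(
            qname = r$qname, first = bitwAnd(flag, 64L) > 0L,
            base = sq[qpos + k - 1L], qual = qq[qpos + k - 1L])))
        }
        gpos <- gpos + n; qpos <- qpos + n
      } else if (o %in% c("D", "N")) {
        gpos <- gpos + n
      } else if (o %in% c("I", "S")) {
        qpos <- qpos + n
      } # H, P: nothing
    }
  }
  rows <- lapply(names(acc), function(key) {
    entries <- acc[[key]]
    # one contribution per fragment: higher quality wins, ties first mate
    qn <- vapply(entries, `[[`, "", "qname")
    best <- list()
    for (e in entries) {
      b <- best[[e$qname]]
      if (is.null(b) || e$qual > b$qual ||
          (e$qual == b$qual && e$first && !b$first))
        best[[e$qname]] <- e
    }
    kept <- Filter(function(e) e$qual >= min_bq &&
                     e$base %in% c("A", "C", "G", "T"), best)
    if (length(kept) == 0L) return(NULL)
    bases <- vapply(kept, `[[`, "", "base")
    quals <- vapply(kept, `[[`, 0L, "qual")
    parts <- strsplit(key, ":")[[1]]
    data.frame(chrom = parts[1], pos = as.integer(parts[2]),
               A = sum(bases == "A"), C = sum(bases == "C"),
               G = sum(bases == "G"), T = sum(bases == "T"),
               coverage = length(bases),
               mean_quality = round(mean(quals), 2))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(chrom = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      coverage = integer(), mean_quality = numeric()))
  rows[order(rows$chrom, rows$pos), , drop = FALSE]
}

# Exact two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, summing point probabilities <= the observed one.
oracle_fisher <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  ks <- max(0L, K - n2):min(n1, K)
  dens <- vapply(ks, function(k)
    choose(n1, k) * choose(n2, K - k) / choose(n1 + n2, K), 0)
  obs <- dens[ks == k1]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Step-up adjustment computed by the literal running-minimum recursion
# from the largest rank down.
oracle_bh <- function(p, m) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  run <- Inf
  for (i in n:1) {
    run <- min(run, ps[i] * m / i)
    adj[i] <- min(1, run)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided rank-sum p by enumerating every assignment of ranks to
# group 1 (no ties assumed).
oracle_ranksum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(n1 + n2, n1)
  ws <- apply(combs, 2, function(idx) sum(seq_len(n1 + n2)[idx]))
  mu <- n1 * (n1 + n2 + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Write a SAM file from a record data.frame and convert it to a sorted,
# indexed BAM; returns the BAM path.
write_test_bam <- function(records, chrom_lengths, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    qual <- rawToChar(as.raw(r$qual[[1]] + 33L))
    tags <- if (!is.na(r$nh)) sprintf("\tNH:i:%d", r$nh) else ""
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
            r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
            r$rnext, r$pnext, r$tlen, r$seq, qual, tags)
  }, "")
  sam <- file.path(dir, "test.sam")
  writeLines(c(hdr, body), sam)
  suppressMessages(Rsamtools::asBam(sam, file.path(dir, "test"),
                                    overwrite = TRUE,
                                    indexDestination = TRUE))
}

# Random mate pairs over a small genome for property tests. Each fragment
# emits a first and a second mate with a shared qname (often overlapping,
# to exercise the one-contribution-per-fragment rule) and a mix of flags,
# MAPQs, base qualities and NH tags.
random_records <- function(n_reads, genome, seed) {
  set.seed(seed)
  L <- nchar(genome[[1]])
  chrom <- names(genome)[1]
  rl <- 10L
  bases <- c("A", "C", "G", "T")
  n_pairs <- ceiling(n_reads / 2)
  recs <- list()
  for (p in seq_len(n_pairs)) {
    pos1 <- sample.int(L - rl + 1L, 1L)
    # mate often overlaps the first read
    pos2 <- min(max(1L, pos1 + sample(-5:8, 1L)), L - rl + 1L)
    proper <- runif(1) < 0.8
    for (m in 1:2) {
      pos <- if (m == 1L) pos1 else pos2
      s <- strsplit(substring(genome[[1]], pos, pos + rl - 1L), "")[[1]]
      nm <- sample(0:2, 1)
      if (nm > 0) {
        at <- sample(rl, nm)
        s[at] <- sample(bases, nm, replace = TRUE)
      }
      flag <- bitwOr(1L, if (m == 1L) 64L else 128L)
      if (proper) flag <- bitwOr(flag, 2L)
      if (runif(1) < 0.15) flag <- bitwOr(flag, 1024L)  # duplicate
      if (runif(1) < 0.15) flag <- bitwOr(flag, 256L)   # secondary
      recs[[length(recs) + 1L]] <- data.frame(
        qname = sprintf("frag%03d", p),
        flag = flag, chrom = chrom, pos = pos,
        mapq = sample(c(60L, 60L, 60L, 30L), 1L), cigar = paste0(rl, "M"),
        rnext = "*", pnext = 0L, tlen = 0L,
        seq = paste(s, collapse = ""),
        qual = I(list(sample(c(40L, 35L, 20L), rl, replace = TRUE))),
        nh = sample(c(NA, 1L, 2L), 1L, prob = c(0.6, 0.3, 0.1))
      )
    }
  }
  do.call(rbind, recs[seq_len(n_reads)])
}

tiny_genome <- function(seed = 11, L = 60L) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
             collapse = "")
  setNames(c(g), "chrT")
}
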