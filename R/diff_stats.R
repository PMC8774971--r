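## The statistical core: per-site 2x2 contingency analysis between cohorts
## with two-sided Fisher exact tests and Benjamini-Hochberg step-up FDR
## correction, and the cohort-level editing-burden comparison with a
## two-sample rank-sum test on library-size-normalized site counts.

#' Bundle per-sample editing profiles
#'
#' A cohort is described by one row per sample (id, group, library size)
#' plus a long table of the sites detected as edited in each sample. A
#' sample counts as edited at a site iff the site survived that sample's
#' calling and filtering — with the default thresholds, one variant read
#' suffices; no per-sample frequency cutoff is applied.
#'
#' @param samples data.frame with columns `sample_id`, `group` (values
#'   `"control"`/`"case"`), `library_size` (mapped reads, > 0).
#' @param edited data.frame with columns `sample_id`, `chrom`, `position`:
#'   one row per (sample, edited site).
#' @return A `sample_profiles` object.
#' @export
sample_profiles <- function(samples, edited) {
  samples <- as.data.table(samples)
  edited <- as.data.table(edited)
  need <- c("sample_id", "group", "library_size")
  if (!all(need %in% names(samples)))
    stop("`samples` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(as.character(samples$group)), c("control", "case"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected \"control\"/\"case\"", call. = FALSE)
  if (any(!is.finite(samples$library_size) | samples$library_size <= 0))
    stop("library sizes must be positive", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in `samples`", call. = FALSE)
  if (nrow(edited)) {
    if (!all(c("sample_id", "chrom", "position") %in% names(edited)))
      stop("`edited` needs columns sample_id, chrom, position",
           call. = FALSE)
    unknown <- setdiff(unique(edited$sample_id), samples$sample_id)
    if (length(unknown))
      stop("edited-site rows for unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    edited <- unique(edited[, .(sample_id, chrom,
                                position = as.integer(position))])
  } else {
    edited <- data.table(sample_id = character(), chrom = character(),
                         position = integer())
  }
  structure(list(samples = samples[], edited = edited[]),
            class = "sample_profiles")
}

#' @export
print.sample_profiles <- function(x, ...) {
  n <- table(factor(x$samples$group, c("control", "case")))
  cat("Sample profiles: ", n[["control"]], " control / ", n[["case"]],
      " case samples; ", nrow(x$edited), " (sample, edited site) records\n",
      sep = "")
  invisible(x)
}

#' Build per-sample profiles from filtered call tables
#'
#' Convenience constructor turning one filtered site-call table per sample
#' into a [sample_profiles()] cohort.
#'
#' @param call_tables Named list (by sample id) of site-call tables.
#' @param groups Character vector (same names/order) of `"control"`/
#'   `"case"` labels.
#' @param library_sizes Numeric vector (same names/order) of mapped-read
#'   counts.
#' @return A `sample_profiles` object.
#' @export
profiles_from_calls <- function(call_tables, groups, library_sizes) {
  ids <- names(call_tables)
  if (is.null(ids)) ids <- paste0("S", seq_along(call_tables))
  samples <- data.table(sample_id = ids, group = as.character(groups),
                        library_size = as.numeric(library_sizes))
  edited <- rbindlist(lapply(seq_along(call_tables), function(i) {
    ct <- as.data.table(call_tables[[i]])
    if (nrow(ct) == 0L)
      return(data.table(sample_id = character(), chrom = character(),
                        position = integer()))
    data.table(sample_id = ids[i], chrom = ct$chrom, position = ct$position)
  }))
  sample_profiles(samples, edited)
}

#' Count edited samples per group at one site
#'
#' @param profiles A [sample_profiles()] cohort.
#' @param site Length-2 vector or list `(chrom, position)`.
#' @return Named integer vector `k_control`, `n_control`, `k_case`,
#'   `n_case`: edited and total samples per group.
#' @export
build_contingency <- function(profiles, site) {
  stopifnot(inherits(profiles, "sample_profiles"))
  ch <- as.character(site[[1L]]); po <- as.integer(site[[2L]])
  ed <- profiles$edited[chrom == ch & position == po, sample_id]
  grp <- profiles$samples$group
  if (!any(grp == "control") || !any(grp == "case"))
    stop("need at least one sample in each group", call. = FALSE)
  isedit <- profiles$samples$sample_id %in% ed
  c(k_control = sum(isedit & grp == "control"),
    n_control = sum(grp == "control"),
    k_case = sum(isedit & grp == "case"),
    n_case = sum(grp == "case"))
}

#' Two-sided Fisher exact test for a 2x2 editing contingency table
#'
#' Exact p-value under the hypergeometric null with fixed margins;
#' two-sided by summing the probabilities of all tables whose point
#' probability does not exceed that of the observed table (the standard
#' exact convention, as in [stats::fisher.test()]).
#'
#' @param k1,n1 Edited and total samples in group 1.
#' @param k2,n2 Edited and total samples in group 2.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(k1, n1, k2, n2) {
  v <- c(k1, n1, k2, n2)
  if (any(is.na(v)) || any(v != round(v)) || any(v < 0) ||
      k1 > n1 || k2 > n2 || n1 + n2 == 0)
    stop("impossible counts: need 0 <= k <= n per group, n1 + n2 > 0",
         call. = FALSE)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg step-up adjustment over a tested family of size m
#'
#' Step-up FDR adjustment `min over j >= i of (p_(j) * m_total / j)`,
#' clamped at 1 and returned in input order. `m_total` may exceed the
#' number of supplied p-values when only the smallest members of the
#' tested family are passed in; the caller is responsible for supplying
#' the `length(p_values)` smallest of the family.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param m_total Size of the tested family (default `length(p_values)`).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values, m_total = length(p_values),
                      method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m_total < length(p_values))
    stop("m_total (", m_total, ") is smaller than the number of supplied ",
         "p-values (", length(p_values), ")", call. = FALSE)
  stats::p.adjust(p_values, method = method, n = m_total)
}

#' Per-site differential-editing table between two cohorts
#'
#' For each site, counts the edited samples in each group, applies the
#' two-sided Fisher exact test, and adjusts the p-values over the full
#' tested family with the Benjamini-Hochberg step-up procedure (Bonferroni
#' available via `method`). Rows are sorted by adjusted p ascending, ties
#' broken by raw p then by (chromosome, position).
#'
#' @param profiles A [sample_profiles()] cohort.
#' @param sites data.frame of sites to test: columns `chrom`, `position`,
#'   optionally `gene`.
#' @param m_total Size of the tested family for the adjustment (default:
#'   number of supplied sites).
#' @param method Multiplicity correction passed to [bh_adjust()].
#' @param alpha Significance level stored for [summary()] and recovery
#'   reporting (default 0.05).
#' @return An object of class `edit_diff` with the per-site table and the
#'   test metadata; see [print.edit_diff()], [summary.edit_diff()],
#'   [as.data.frame.edit_diff()], [plot.edit_diff()].
#' @export
differential_table <- function(profiles, sites, m_total = NULL,
                               method = c("BH", "bonferroni"),
                               alpha = 0.05) {
  stopifnot(inherits(profiles, "sample_profiles"))
  method <- match.arg(method)
  sites <- unique(as.data.table(sites), by = c("chrom", "position"))
  if (nrow(sites) == 0L) stop("no sites to test", call. = FALSE)
  if (!"gene" %in% names(sites)) sites[, gene := NA_character_]
  if (is.null(m_total)) m_total <- nrow(sites)

  grp <- profiles$samples$group
  n_ctrl <- sum(grp == "control"); n_case <- sum(grp == "case")
  if (n_ctrl == 0L || n_case == 0L)
    stop("need at least one sample in each group", call. = FALSE)

  ed <- merge(profiles$edited,
              profiles$samples[, .(sample_id, group)], by = "sample_id")
  cnt <- ed[, .(k_control = sum(group == "control"),
                k_case = sum(group == "case")), by = .(chrom, position)]
  tab <- merge(sites[, .(gene, chrom, position = as.integer(position))],
               cnt, by = c("chrom", "position"), all.x = TRUE)
  tab[is.na(k_control), k_control := 0L]
  tab[is.na(k_case), k_case := 0L]
  tab[, `:=`(n_control = n_ctrl, n_case = n_case)]
  tab[, p_fisher := mapply(fisher_exact_two_sided,
                           k_control, n_control, k_case, n_case)]
  tab[, p_adjusted := bh_adjust(p_fisher, m_total = m_total,
                                method = method)]
  setorderv(tab, c("p_adjusted", "p_fisher", "chrom", "position"))
  setcolorder(tab, c("gene", "chrom", "position", "k_control", "n_control",
                     "k_case", "n_case", "p_fisher", "p_adjusted"))
  structure(list(table = tab[], m_total = m_total, method = method,
                 alpha = alpha, n_control = n_ctrl, n_case = n_case),
            class = "edit_diff")
}

#' @export
print.edit_diff <- function(x, n = 10L, ...) {
  cat("Differential A-to-I editing: ", nrow(x$table), " sites tested (",
      x$n_control, " control vs ", x$n_case, " case samples), ",
      x$method, " correction over m = ", x$m_total, "\n", sep = "")
  sig <- sum(x$table$p_adjusted <= x$alpha)
  cat(sig, " site(s) significant at adjusted p <= ", x$alpha, "\n\n",
      sep = "")
  show <- head(copy(x$table), n)
  show[, `:=`(p_fisher = formatC(p_fisher, format = "e", digits = 2),
              p_adjusted = formatC(p_adjusted, format = "e", digits = 2))]
  print(show, row.names = FALSE)
  if (nrow(x$table) > n)
    cat("... and", nrow(x$table) - n, "more rows\n")
  invisible(x)
}

#' @export
summary.edit_diff <- function(object, ...) {
  tab <- object$table
  out <- list(
    n_sites = nrow(tab),
    n_significant = sum(tab$p_adjusted <= object$alpha),
    alpha = object$alpha, method = object$method, m_total = object$m_total,
    n_control = object$n_control, n_case = object$n_case,
    higher_in_control = sum(tab$k_control / tab$n_control >
                              tab$k_case / tab$n_case),
    higher_in_case = sum(tab$k_control / tab$n_control <
                           tab$k_case / tab$n_case)
  )
  class(out) <- "summary.edit_diff"
  out
}

#' @export
print.summary.edit_diff <- function(x, ...) {
  cat("Sites tested:        ", x$n_sites, "\n")
  cat("Significant (p.adj <=", x$alpha, "):", x$n_significant, "\n")
  cat("Correction:          ", x$method, "over m =", x$m_total, "\n")
  cat("Cohort sizes:        ", x$n_control, "control /", x$n_case, "case\n")
  cat("Edited more in controls:", x$higher_in_control,
      " in cases:", x$higher_in_case, "\n")
  invisible(x)
}

#' @export
as.data.frame.edit_diff <- function(x, ...) {
  as.data.frame(x$table, ...)
}

#' Volcano-style plot of a differential-editing table
#'
#' Plots the difference in edited-sample proportion (case minus control)
#' against `-log10` adjusted p, marking the significance level.
#'
#' @param x An `edit_diff` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.edit_diff <- function(x, ...) {
  tab <- x$table
  dx <- tab$k_case / tab$n_case - tab$k_control / tab$n_control
  dy <- -log10(pmax(tab$p_adjusted, .Machine$double.xmin))
  graphics::plot(dx, dy,
                 xlab = "edited-sample proportion: case - control",
                 ylab = expression(-log[10] ~ "adjusted p"),
                 pch = 19, col = ifelse(tab$p_adjusted <= x$alpha,
                                        "firebrick", "grey40"), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Two-sample rank-sum (Mann-Whitney) test, two-sided
#'
#' Exact enumeration when the pooled sample size is at most `exact_max`
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values_control,values_case Non-empty numeric vectors.
#' @param exact_max Pooled-size limit for the exact test (default 25).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(values_control, values_case,
                              exact_max = 25L) {
  x <- as.numeric(values_control); y <- as.numeric(values_case)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= exact_max
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Per-sample editing burden and cohort comparison
#'
#' Counts each sample's detected edited sites, normalizes to sites per
#' million mapped reads, and compares the two cohorts with the two-sided
#' rank-sum test on both the raw and the normalized counts (raw counts
#' track library size, so the normalized comparison is the meaningful
#' one; both are reported).
#'
#' @param profiles A [sample_profiles()] cohort.
#' @return An object of class `edit_burden`: per-sample table
#'   (`sample_id`, `group`, `n_sites`, `library_size`,
#'   `sites_per_million`), group medians, and rank-sum p-values `p_raw`
#'   and `p_normalized`.
#' @export
edit_burden <- function(profiles) {
  stopifnot(inherits(profiles, "sample_profiles"))
  cnt <- profiles$edited[, .(n_sites = .N), by = sample_id]
  per <- merge(profiles$samples, cnt, by = "sample_id", all.x = TRUE)
  per[is.na(n_sites), n_sites := 0L]
  per[, sites_per_million := n_sites * 1e6 / library_size]
  setorder(per, group, sample_id)
  ctrl <- per[group == "control"]; case <- per[group == "case"]
  if (nrow(ctrl) == 0L || nrow(case) == 0L)
    stop("need at least one sample in each group", call. = FALSE)
  structure(list(
    per_sample = per[],
    medians = list(
      raw = c(control = median(ctrl$n_sites), case = median(case$n_sites)),
      normalized = c(control = median(ctrl$sites_per_million),
                     case = median(case$sites_per_million))
    ),
    p_raw = wilcoxon_rank_sum(ctrl$n_sites, case$n_sites),
    p_normalized = wilcoxon_rank_sum(ctrl$sites_per_million,
                                     case$sites_per_million)
  ), class = "edit_burden")
}

#' @rdname edit_burden
#' @param profiles A [sample_profiles()] cohort.
#' @export
burden_per_sample <- function(profiles) edit_burden(profiles)

#' @export
print.edit_burden <- function(x, ...) {
  m <- x$medians
  cat("Editing burden (", sum(x$per_sample$group == "control"),
      " control vs ", sum(x$per_sample$group == "case"), " case)\n",
      sep = "")
  cat(sprintf("  median sites: control %.1f, case %.1f (raw)\n",
              m$raw["control"], m$raw["case"]))
  cat(sprintf("  median sites/M reads: control %.3f, case %.3f\n",
              m$normalized["control"], m$normalized["case"]))
  cat(sprintf("  rank-sum p: raw %.4g, normalized %.4g\n",
              x$p_raw, x$p_normalized))
  invisible(x)
}

#' Boxplot of per-sample normalized editing burden by group
#'
#' @param x An `edit_burden` object.
#' @param normalized Plot sites per million mapped reads (default) or raw
#'   counts.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.edit_burden <- function(x, normalized = TRUE, ...) {
  per <- x$per_sample
  val <- if (normalized) per$sites_per_million else per$n_sites
  graphics::boxplot(val ~ factor(per$group, c("control", "case")),
                    xlab = "", ylab = if (normalized)
                      "edited sites per million mapped reads"
                    else "edited sites", ...)
  invisible(x)
}
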