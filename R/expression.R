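#' Relative qPCR expression (Livak 2^-dCt / 2^-ddCt)
#'
#' Computes relative expression from a long-format Ct table. Technical
#' replicates are first averaged to one Ct per sample x gene (arithmetic
#' mean of Ct, the standard Livak usage). For each target gene,
#' dCt = Ct_target - Ct_reference per sample and relative expression
#' 2^-dCt. With `method = "ddct"`, ddCt = dCt - mean dCt of the control
#' group (per gene) and fold change 2^-ddCt; the control group's own mean
#' fold is then exactly 1 in log space. When exactly two groups are
#' present with >= 3 samples each, a normality-gated two-sample
#' comparison ([compare_groups()]) is attached per gene.
#'
#' @param ct data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct` (cycles, > 0).
#' @param reference_gene the endogenous control gene (default `"RPL32"`,
#'   the standard reference in the diamondback moth).
#' @param method `"dct"` or `"ddct"`.
#' @param control_group required for `"ddct"`: the baseline group name.
#' @return object of class `expression_result`: list with `samples`
#'   (per-sample data.frame: `sample_id`, `group`, `gene`, `ct_target`,
#'   `ct_ref`, `dct`, `relative_2dct`, and for ddct also `ddct`,
#'   `fold_change`), `comparisons` (per-gene test results or NULL),
#'   `method`, `reference_gene`.
#' @export
relative_expression <- function(ct, reference_gene = "RPL32",
                                method = c("dct", "ddct"),
                                control_group = NULL) {
  method <- match.arg(method)
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    stop("schema error: Ct table missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(ct$ct <= 0)) {
    stop("validation error: Ct values must be > 0", call. = FALSE)
  }
  if (!(reference_gene %in% ct$gene)) {
    stop("schema error: reference gene '", reference_gene,
         "' absent from Ct table", call. = FALSE)
  }
  if (method == "ddct" && is.null(control_group)) {
    stop("config error: ddct requires control_group", call. = FALSE)
  }

  # technical replicates -> one Ct per sample x gene
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct,
                          FUN = mean)
  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  tgt <- agg[agg$gene != reference_gene, ]
  if (nrow(tgt) == 0) {
    stop("validation error: no target genes in Ct table", call. = FALSE)
  }
  no_ref <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(no_ref)) {
    stop("schema error: sample(s) without reference-gene rows: ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  }
  names(tgt)[names(tgt) == "ct"] <- "ct_target"
  res <- merge(tgt, ref, by = "sample_id", sort = FALSE)
  res$dct <- res$ct_target - res$ct_ref
  res$relative_2dct <- 2^(-res$dct)

  if (method == "ddct") {
    if (!(control_group %in% res$group)) {
      stop("config error: control_group '", control_group,
           "' has no samples", call. = FALSE)
    }
    base <- stats::aggregate(dct ~ gene,
                             data = res[res$group == control_group, ],
                             FUN = mean)
    names(base)[2] <- "dct_control"
    res <- merge(res, base, by = "gene", sort = FALSE)
    res$ddct <- res$dct - res$dct_control
    res$fold_change <- 2^(-res$ddct)
    res$dct_control <- NULL
  }
  res <- res[order(res$gene, res$group, res$sample_id), ]
  rownames(res) <- NULL

  comparisons <- NULL
  groups <- unique(res$group)
  if (length(groups) == 2) {
    comparisons <- do.call(rbind, lapply(split(res, res$gene), function(g) {
      va <- g$relative_2dct[g$group == groups[1]]
      vb <- g$relative_2dct[g$group == groups[2]]
      if (length(va) >= 3 && length(vb) >= 3) {
        cmp <- compare_groups(va, vb)
        data.frame(gene = g$gene[1], group_a = groups[1],
                   group_b = groups[2], test_used = cmp$test_used,
                   p_value = cmp$p_value, stringsAsFactors = FALSE)
      } else {
        NULL
      }
    }))
    if (!is.null(comparisons)) rownames(comparisons) <- NULL
  }

  structure(list(samples = res, comparisons = comparisons,
                 method = method, reference_gene = reference_gene),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat("<expression_result> method 2^-", toupper(sub("ct", "Ct", x$method)),
      ", reference ", x$reference_gene, "\n", sep = "")
  print(x$samples, digits = 4)
  if (!is.null(x$comparisons)) {
    cat("group comparisons:\n")
    print(x$comparisons, digits = 4)
  }
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' The published decision rule: Shapiro-Wilk on each group at alpha =
#' 0.05; if both pass, a two-sample t-test (Welch form, no equal-variance
#' assumption; group sizes here are 3-5); otherwise the Mann-Whitney
#' U-test. Groups whose Shapiro-Wilk test cannot run (e.g. zero
#' within-group variance) are treated as non-normal.
#'
#' @param values_a,values_b numeric vectors, >= 3 values each.
#' @return list with `test_used` (`"welch_t"` or `"mann_whitney"`),
#'   `p_value`, and the two Shapiro-Wilk p-values (`shapiro_p`, NA when
#'   the test could not run).
#' @export
#' @examples
#' compare_groups(c(1.0, 1.2, 0.9, 1.1), c(2.1, 2.0, 2.3, 1.9))
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("insufficient data: need >= 3 values per group", call. = FALSE)
  }
  sw <- function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  pa <- sw(values_a)
  pb <- sw(values_b)
  normal <- !is.na(pa) && !is.na(pb) && pa >= 0.05 && pb >= 0.05
  if (normal) {
    pv <- stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
    test <- "welch_t"
  } else {
    pv <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE)$p.value)
    test <- "mann_whitney"
  }
  list(test_used = test, p_value = pv, shapiro_p = c(a = pa, b = pb))
}
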