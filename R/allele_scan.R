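# Single-allele resolution detector: for each gained allele B with a known
# phylogenetic origin, a binomial logistic regression of the per-branch
# loss indicator on allele age, with log branch length as an exposure
# offset.  A positive age slope means the allele is replaced more often the
# longer it has been resident (senescence); a negative slope means
# replacement concentrates just after the gain (entrenchment).

#' Test one allele for age-dependent replacement
#'
#' Fits `s ~ age + offset(log(length))` with a binomial likelihood on the
#' member branches of one substitution subtree and reports the two-sided
#' Wald (or likelihood-ratio) p-value of the age slope.  Subtrees with
#' fewer than two distinct ages, with all losses or all survivals, or with
#' complete separation are flagged untestable rather than given a p-value.
#'
#' @param branches Data frame of the subtree's member branches with columns
#'   `length`, `age`, `s`.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return A one-row data frame: `slope`, `p_value`, `n_branches`,
#'   `testable`.
#' @export
test_allele <- function(branches, test = c("wald", "lrt")) {
  test <- match.arg(test)
  branches <- as.data.frame(branches)
  out <- data.frame(slope = NA_real_, p_value = NA_real_,
                    n_branches = nrow(branches), testable = FALSE)
  if (nrow(branches) < 2 ||
      length(unique(branches$age)) < 2 ||
      all(branches$s == 0) || all(branches$s == 1) ||
      any(branches$length <= 0))
    return(out)
  fit <- suppressWarnings(tryCatch(
    glm(s ~ age + offset(log(length)), family = binomial(),
        data = branches),
    error = function(e) NULL))
  if (is.null(fit) || !fit$converged) return(out)
  slope <- coef(fit)[["age"]]
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[["age"]])
  if (!is.finite(slope) || !is.finite(se) || abs(slope) > 1e3 || se > 1e3)
    return(out)  # separation: slope diverges
  p <- if (test == "wald") {
    2 * pnorm(-abs(slope / se))
  } else {
    null_fit <- suppressWarnings(
      glm(s ~ 1 + offset(log(length)), family = binomial(), data = branches))
    stats::pchisq(null_fit$deviance - fit$deviance, df = 1,
                  lower.tail = FALSE)
  }
  data.frame(slope = slope, p_value = p, n_branches = nrow(branches),
             testable = TRUE)
}

#' Scan all alleles for senescence and entrenchment
#'
#' Tests every substitution subtree whose gained allele has a known origin
#' (alleles already present at the tree root have no gain branch and are
#' never part of a subtree, so the eligibility restriction is inherited
#' from the extraction step), applies Benjamini-Hochberg FDR control across
#' the testable alleles, and assigns verdicts: `senescing` for significant
#' positive slopes, `entrenched` for significant negative slopes, `ns`
#' otherwise.
#'
#' @param subtrees A `subtree_set` from [extract_subtrees()].
#' @param fdr False-discovery-rate threshold (default 0.05).
#' @param test Passed to [test_allele()].
#' @return Data frame of class `allele_scan` with one row per subtree:
#'   site, allele, gain branch, slope, p, q, verdict.
#' @export
allele_scan <- function(subtrees, fdr = 0.05, test = "wald") {
  stopifnot(inherits(subtrees, "subtree_set"))
  info <- subtrees$subtrees
  if (!nrow(info)) {
    out <- data.frame(site = character(), allele = character(),
                      gain_branch = character(), slope = numeric(),
                      p = numeric(), q = numeric(), verdict = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("allele_scan", "data.frame")
    return(out)
  }
  tests <- do.call(rbind, lapply(seq_len(nrow(info)), function(i) {
    br <- subtrees$branches[subtrees$branches$subtree == info$subtree[i], ]
    test_allele(br, test)
  }))
  out <- data.frame(site = info$site, allele = info$B,
                    gain_branch = info$gain_branch,
                    slope = tests$slope, p = tests$p_value,
                    q = NA_real_, verdict = "untestable",
                    n_branches = tests$n_branches,
                    stringsAsFactors = FALSE)
  ok <- tests$testable
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out$verdict[ok] <- ifelse(out$q[ok] <= fdr,
                            ifelse(out$slope[ok] > 0, "senescing", "entrenched"),
                            "ns")
  attr(out, "fdr") <- fdr
  class(out) <- c("allele_scan", "data.frame")
  out
}

#' @export
print.allele_scan <- function(x, ...) {
  cat("Allele scan:", nrow(x), "alleles;",
      sum(x$verdict == "senescing"), "senescing,",
      sum(x$verdict == "entrenched"), "entrenched at",
      attr(x, "fdr") * 100, "% FDR (",
      sum(x$verdict == "untestable"), "untestable )\n")
  invisible(x)
}

#' Compare substitution counts between senescing and entrenched sites
#'
#' For sites carrying at least one significantly senescing or entrenched
#' allele, compares per-site substitution counts (number of subtrees, i.e.
#' internal-branch substitutions, plus observed losses) between the two
#' classes with a two-sided sign test on the pooled counts.  Diagnostic
#' only: similar counts indicate the overall substitution rate cannot
#' separate the two regimes.
#'
#' @param scan An `allele_scan` result.
#' @param subtrees The `subtree_set` the scan was run on.
#' @return List with `counts` (per-site class and substitution count) and
#'   `p_value` of the sign test comparing the two classes to their common
#'   median.
#' @export
substitution_count_comparison <- function(scan, subtrees) {
  info <- subtrees$subtrees
  per_site <- aggregate(cbind(subs = info$n_branches * 0 + 1 + info$n_losses)
                        ~ site, data = info, FUN = sum)
  cls <- vapply(per_site$site, function(s) {
    v <- scan$verdict[scan$site == s]
    if (any(v == "senescing")) "senescing"
    else if (any(v == "entrenched")) "entrenched" else "ns"
  }, "")
  per_site$class <- cls
  sen <- per_site$subs[cls == "senescing"]
  ent <- per_site$subs[cls == "entrenched"]
  if (!length(sen) || !length(ent))
    stop("need at least one site in each class")
  m <- median(c(sen, ent))
  above <- sum(sen > m) + sum(ent < m)
  below <- sum(sen < m) + sum(ent > m)
  p <- if (above + below == 0) 1 else
    binom.test(above, above + below)$p.value
  list(counts = per_site[per_site$class != "ns", ], p_value = p)
}
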