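#' Default substring blacklist for bulk RNA-seq gene prefiltering
#'
#' Case-sensitive tokens whose occurrence anywhere in a gene symbol flags the
#' gene for removal: ribosomal/mitoribosomal (Mrp, Rpl, Rps), spliceosomal and
#' general transcription machinery (Sn, Sf, Gtf, Med, Rbm), murine
#' placeholder symbols (Rik, Gm), oxidative-phosphorylation and
#' mitochondrial-import machinery (Atp, Nduf, Tomm, Timm, Micos, Bola),
#' polymerase and nucleic-acid processing (Pol, Rna, Dna, Ddx, Anap) and
#' small integral membrane proteins (Smim). Short tokens such as `Sn` are
#' deliberately aggressive; the list is applied verbatim.
#'
#' @return Character vector of tokens, in match-priority order.
#' @export
default_substring_blacklist <- function() {
  c("Mrp", "Rpl", "Rps", "Sn", "Sf", "Gtf", "Med", "Rbm", "Rik", "Atp",
    "Nduf", "Tomm", "Pol", "Anap", "Rna", "Dna", "Gm", "Ddx", "Smim",
    "Bola", "Timm", "Micos")
}

#' Remove genes whose symbols contain blacklisted substrings
#'
#' A gene is removed iff any token occurs case-sensitively anywhere in its
#' symbol; the first matching token (in list order) is recorded as the
#' removal reason. Kept and removed sets partition the input.
#'
#' @param genes character vector of gene symbols.
#' @param blacklist character vector of tokens; defaults to
#'   [default_substring_blacklist()].
#' @return List with `kept` (character vector) and `removed` (data frame
#'   `gene`, `reason`).
#' @examples
#' substring_filter(c("Rpl13", "Cd74", "Snca"))
#' @export
substring_filter <- function(genes, blacklist = default_substring_blacklist()) {
  genes <- as.character(genes)
  if (length(blacklist) == 0L) {
    warning("empty blacklist: substring filter is the identity")
    return(list(kept = genes,
                removed = data.frame(gene = character(), reason = character())))
  }
  if (any(!nzchar(blacklist))) stop("blacklist tokens must be nonempty")
  reason <- rep(NA_character_, length(genes))
  for (tok in blacklist) {
    hit <- is.na(reason) & grepl(tok, genes, fixed = TRUE)
    reason[hit] <- tok
  }
  list(kept = genes[is.na(reason)],
       removed = data.frame(gene = genes[!is.na(reason)],
                            reason = reason[!is.na(reason)]))
}

#' Remove lowly expressed genes from a count matrix
#'
#' Two rules are provided. `fraction_rule`: a gene is removed iff its count
#' is below `count_threshold` (default 10) in at least `sample_fraction`
#' (default 0.75) of samples; with `row_sum = TRUE` the alternative reading
#' (total count across samples below `count_threshold`) is applied instead.
#' `total_rule`: a gene is removed iff its total count across samples is
#' strictly below half the number of samples.
#'
#' @param counts numeric gene-by-sample matrix with gene symbols as rownames.
#' @param rule `"fraction_rule"` or `"total_rule"`.
#' @param count_threshold per-sample count threshold of the fraction rule.
#' @param sample_fraction fraction of samples in `(0, 1]`.
#' @param row_sum use the row-sum reading of the fraction rule.
#' @return List with `kept` (submatrix) and `removed` (character vector of
#'   symbols).
#' @examples
#' m <- rbind(lowA = c(0, 2, 3, 50), okB = c(12, 12, 0, 0))
#' colnames(m) <- paste0("s", 1:4)
#' low_expression_filter(m)$removed  # "lowA"
#' @export
low_expression_filter <- function(counts, rule = c("fraction_rule", "total_rule"),
                                  count_threshold = 10, sample_fraction = 0.75,
                                  row_sum = FALSE) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (rule == "fraction_rule") {
    if (sample_fraction <= 0 || sample_fraction > 1) {
      stop("sample_fraction must lie in (0, 1]")
    }
    if (count_threshold <= 0) stop("count_threshold must be positive")
    drop <- if (row_sum) {
      rowSums(counts) < count_threshold
    } else {
      rowMeans(counts < count_threshold) >= sample_fraction
    }
  } else {
    drop <- rowSums(counts) < ncol(counts) / 2
  }
  list(kept = counts[!drop, , drop = FALSE],
       removed = rownames(counts)[drop])
}

#' Bundle gene-prefilter rules into a specification
#'
#' @param substring_blacklist tokens for [substring_filter()]; default the
#'   printed blacklist.
#' @param pathway_gene_sets named list of gene-symbol vectors to remove
#'   wholesale (e.g. ribosome or oxidative-phosphorylation pathway members).
#' @param biotype_blacklist character vector of biotype labels to remove
#'   (e.g. `"pseudogene"`, `"lincRNA"`, `"miRNA"`, `"snRNA"`, `"snoRNA"`,
#'   `"predicted"`); requires a gene-to-biotype map at application time.
#' @param low_expression_rule `"none"`, `"fraction_rule"` or `"total_rule"`.
#' @param count_threshold,sample_fraction,row_sum fraction-rule parameters,
#'   see [low_expression_filter()].
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(substring_blacklist = default_substring_blacklist(),
                        pathway_gene_sets = list(),
                        biotype_blacklist = character(),
                        low_expression_rule = c("none", "fraction_rule",
                                                "total_rule"),
                        count_threshold = 10, sample_fraction = 0.75,
                        row_sum = FALSE) {
  low_expression_rule <- match.arg(low_expression_rule)
  if (length(substring_blacklist) > 0 && any(!nzchar(substring_blacklist))) {
    stop("blacklist tokens must be nonempty")
  }
  if (count_threshold <= 0) stop("count_threshold must be positive")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must lie in (0, 1]")
  }
  structure(list(substring_blacklist = substring_blacklist,
                 pathway_gene_sets = pathway_gene_sets,
                 biotype_blacklist = biotype_blacklist,
                 low_expression_rule = low_expression_rule,
                 count_threshold = count_threshold,
                 sample_fraction = sample_fraction, row_sum = row_sum),
            class = "filter_spec")
}

#' Apply a full prefilter specification to a count matrix
#'
#' Filters are applied in fixed order: pathway gene sets, then biotypes, then
#' substring blacklist, then the low-expression rule. Every removed gene is
#' logged once with the stage and reason of its removal; kept plus removed
#' genes always partition the input, and reapplying the same spec to the
#' result is the identity.
#'
#' @param counts numeric gene-by-sample matrix, symbols as rownames.
#' @param spec a [filter_spec()].
#' @param biotypes optional named character vector mapping gene symbols to
#'   biotypes; required only when `spec$biotype_blacklist` is nonempty.
#' @return List with `counts` (filtered matrix) and `audit` (data frame
#'   `gene`, `stage`, `reason`, one row per removed gene).
#' @export
apply_filter_spec <- function(counts, spec, biotypes = NULL) {
  stopifnot(inherits(spec, "filter_spec"), is.matrix(counts),
            !is.null(rownames(counts)))
  audit <- list(); j <- 0L
  log_removed <- function(genes, stage, reason) {
    if (length(genes) == 0L) return()
    j <<- j + 1L
    audit[[j]] <<- data.frame(gene = genes, stage = stage, reason = reason,
                              stringsAsFactors = FALSE)
  }
  for (ps in names(spec$pathway_gene_sets)) {
    set <- spec$pathway_gene_sets[[ps]]
    absent <- setdiff(set, rownames(counts))
    if (length(absent) > 0L) {
      warning(sprintf("pathway set '%s': %d gene(s) not in the matrix", ps,
                      length(absent)))
    }
    hit <- intersect(rownames(counts), set)
    log_removed(hit, "pathway", ps)
    counts <- counts[setdiff(rownames(counts), hit), , drop = FALSE]
  }
  if (length(spec$biotype_blacklist) > 0L) {
    if (is.null(biotypes)) {
      stop("biotype_blacklist set but no gene-to-biotype map supplied")
    }
    bt <- biotypes[rownames(counts)]
    hit <- rownames(counts)[!is.na(bt) & bt %in% spec$biotype_blacklist]
    log_removed(hit, "biotype", unname(biotypes[hit]))
    counts <- counts[setdiff(rownames(counts), hit), , drop = FALSE]
  }
  if (length(spec$substring_blacklist) > 0L) {
    sf <- substring_filter(rownames(counts), spec$substring_blacklist)
    log_removed(sf$removed$gene, "substring", sf$removed$reason)
    counts <- counts[sf$kept, , drop = FALSE]
  }
  if (spec$low_expression_rule != "none" && nrow(counts) > 0L) {
    lf <- low_expression_filter(counts, spec$low_expression_rule,
                                spec$count_threshold, spec$sample_fraction,
                                spec$row_sum)
    log_removed(lf$removed, "low_expression", spec$low_expression_rule)
    counts <- lf$kept
  }
  audit <- if (j == 0L) {
    data.frame(gene = character(), stage = character(), reason = character())
  } else do.call(rbind, audit)
  list(counts = counts, audit = audit)
}
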