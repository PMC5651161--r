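#' Overall activator/repressor polarity of transcription factors
#'
#' A TF's polarity is the algebraic sum of its outgoing interactions. In
#' `"sign"` mode (the default) each positively-weighted target counts +1 and
#' each negatively-weighted target -1, so the score is
#' `n_positive - n_negative`; in `"weight"` mode the raw weights are summed.
#' A positive score labels the TF an overall activator, a negative one an
#' overall repressor, zero is neutral. Zero-weight ("dual") edges count
#' toward the out-degree but never move the score in either mode.
#'
#' @param object a `RegulatoryNetwork`.
#' @param gene a gene symbol present in the network.
#' @param mode `"sign"` or `"weight"`.
#' @return `polarityScore()`: one-row data.frame with columns `gene`,
#'   `n_positive`, `n_negative`, `n_neutral`, `score`, `label`.
#'   `polarityTable()`: one row per TF (out-degree > 0) with both
#'   `score_sign` and `score_weight` columns plus `score`/`label` for the
#'   requested mode, sorted by score descending (ties by gene symbol).
#' @examples
#' net <- regulatoryNetwork(edges = data.frame(
#'   source = "TF1", target = c("A", "B", "C"),
#'   weight = c(2.5, -1.0, -0.5)))
#' polarityScore(net, "TF1", mode = "weight")  # 1.0, overall_activator
#' polarityScore(net, "TF1", mode = "sign")    # -1, overall_repressor
#' @export
polarityScore <- function(object, gene, mode = c("sign", "weight")) {
  mode <- match.arg(mode)
  stopifnot(is(object, "RegulatoryNetwork"))
  gene <- .trimws1(gene)
  if (length(gene) != 1L || !gene %in% geneIds(object))
    .lookupError(sprintf("unknown gene: %s", paste(gene, collapse = ", ")),
                 symbols = gene)
  tab <- .polarityCounts(object)
  row <- tab[tab$gene == gene, , drop = FALSE]
  if (!nrow(row))   # gene with no targets
    row <- data.frame(gene = gene, n_positive = 0L, n_negative = 0L,
                      n_neutral = 0L, score_sign = 0, score_weight = 0,
                      stringsAsFactors = FALSE)
  score <- if (mode == "sign") row$score_sign else row$score_weight
  data.frame(gene = gene,
             n_positive = row$n_positive, n_negative = row$n_negative,
             n_neutral = row$n_neutral,
             score = score, label = .polarityLabel(score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname polarityScore
#' @export
polarityTable <- function(object, mode = c("sign", "weight")) {
  mode <- match.arg(mode)
  stopifnot(is(object, "RegulatoryNetwork"))
  tab <- .polarityCounts(object)
  tab$score <- if (mode == "sign") tab$score_sign else tab$score_weight
  tab$label <- .polarityLabel(tab$score)
  o <- order(-tab$score, tab$gene, method = "radix")
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.polarityLabel <- function(score) {
  ifelse(score > 0, "overall_activator",
         ifelse(score < 0, "overall_repressor", "neutral"))
}

## Outgoing-edge sign counts and both score modes, one row per TF.
.polarityCounts <- function(object) {
  e <- edgeTable(object)
  if (!nrow(e))
    return(data.frame(gene = character(0), n_positive = integer(0),
                      n_negative = integer(0), n_neutral = integer(0),
                      score_sign = numeric(0), score_weight = numeric(0),
                      stringsAsFactors = FALSE))
  src <- factor(e$source)
  np <- tapply(e$weight > 0, src, sum)
  nn <- tapply(e$weight < 0, src, sum)
  nz <- tapply(e$weight == 0, src, sum)
  sw <- tapply(e$weight, src, sum)
  data.frame(gene = levels(src),
             n_positive = as.integer(np), n_negative = as.integer(nn),
             n_neutral = as.integer(nz),
             score_sign = as.numeric(np - nn),
             score_weight = as.numeric(sw),
             stringsAsFactors = FALSE, row.names = NULL)
}
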