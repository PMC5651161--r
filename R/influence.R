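#' Relative influence of a gene from its in- and out-degree
#'
#' The relative influence (RI) of gene *n* balances how many genes it
#' regulates against how many regulate it:
#'
#' \deqn{RI_n = \frac{outDeg_n}{inDeg_n + outDeg_n} -
#'       \frac{\epsilon + inDeg_n}{\epsilon + outDeg_n}}
#'
#' where \eqn{\epsilon} is a small positive constant (default `1e-3`)
#' guarding the division by zero for effector genes. Unregulated hubs score
#' just below 1; genes with many regulators and few targets score near or
#' below 0. By convention negative values are clipped to 0 in reported
#' tables, and an isolated gene (both degrees zero) has RI 0.
#'
#' @param inDeg,outDeg non-negative degree counts (vectorised, recycled).
#' @param epsilon small positive regulariser. The reported human (FANTOM4)
#'   tables use `1e-3`; the *E. coli* (RegulonDB) table values are consistent
#'   with `1e-4` — see the package vignette.
#' @param clip if `TRUE`, negative values are set to 0 (the convention used
#'   in all reported tables). Default `FALSE`: the raw statistic.
#' @return numeric vector of RI values.
#' @examples
#' relativeInfluence(0, 2175)              # 0.99999954...
#' relativeInfluence(232, 2829)            # the GABPB2 worked value
#' relativeInfluence(100, 1, clip = TRUE)  # 0: many regulators, one target
#' @export
relativeInfluence <- function(inDeg, outDeg, epsilon = 1e-3, clip = FALSE) {
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    .usageError("epsilon must be a single positive number")
  inDeg <- as.numeric(inDeg); outDeg <- as.numeric(outDeg)
  if (any(!is.finite(inDeg)) || any(!is.finite(outDeg)) ||
      any(inDeg < 0) || any(outDeg < 0))
    .usageError("degrees must be finite and non-negative")
  n <- max(length(inDeg), length(outDeg))
  inDeg <- rep_len(inDeg, n); outDeg <- rep_len(outDeg, n)
  ri <- outDeg / (inDeg + outDeg) - (epsilon + inDeg) / (epsilon + outDeg)
  ri[inDeg == 0 & outDeg == 0] <- 0   # isolated genes are non-influential
  if (clip) ri <- pmax(ri, 0)
  ri
}

#' Relative-influence table for every gene of a network
#'
#' Computes degrees and RI for every node and returns them ranked by
#' influence (descending RI, ties broken by gene symbol for reproducible
#' tables).
#'
#' @param object a `RegulatoryNetwork`.
#' @param epsilon passed to [relativeInfluence()].
#' @param clipNegative clip negative RI to 0 (default, matching the reported
#'   tables).
#' @return data.frame with columns `gene`, `in_degree`, `out_degree`, `ri`.
#' @examples
#' net <- regulatoryNetwork(edges = data.frame(
#'   source = "TF1", target = paste0("G", 1:8), weight = 1))
#' influenceTable(net)
#' @export
influenceTable <- function(object, epsilon = 1e-3, clipNegative = TRUE) {
  stopifnot(is(object, "RegulatoryNetwork"))
  d <- degrees(object)
  d$ri <- relativeInfluence(d$in_degree, d$out_degree, epsilon,
                            clip = clipNegative)
  o <- order(-d$ri, d$gene, method = "radix")
  d <- d[o, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Top-k and bottom-k genes of an influence table
#'
#' @param records an influence table as returned by [influenceTable()].
#' @param k how many rows for each end (a `k` beyond the table size returns
#'   the whole table).
#' @param restrictToTFs drop effector rows (`out_degree == 0`) before
#'   selecting, so both ends list transcription factors only (the convention
#'   of the reported top/bottom tables).
#' @return list with elements `top` (descending RI) and `bottom` (ascending
#'   RI).
#' @export
topBottom <- function(records, k, restrictToTFs = TRUE) {
  if (length(k) != 1L || is.na(k) || k < 1)
    .usageError("k must be a positive integer")
  if (restrictToTFs)
    records <- records[records$out_degree > 0L, , drop = FALSE]
  o <- order(-records$ri, records$gene, method = "radix")
  records <- records[o, , drop = FALSE]
  n <- nrow(records)
  k <- min(as.integer(k), n)
  top <- records[seq_len(k), , drop = FALSE]
  bottom <- records[rev(seq.int(n - k + 1L, length.out = k)), , drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  list(top = top, bottom = bottom)
}
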