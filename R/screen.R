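# Stage-0 discovery screen: rank short, putatively secreted proteins by
# elicitor-induced transcript accumulation.

#' Screen a proteome for short, secreted, elicitor-induced proteins
#'
#' Keeps proteins strictly shorter than `max_len` residues, optionally
#' requires a positive signal-peptide call, and ranks the survivors by
#' descending log2 fold-change in the chosen expression column (ties
#' broken by id).  Induction is treated as a rank, not a threshold; an
#' optional `min_log2fc` cut is available for pipeline use.
#'
#' Proteins without an expression row (annotation gaps are common for
#' short peptide genes) are retained with `NA` fold-change, sorted last,
#' and reported via a warning.
#'
#' @param proteome a [seq_set()] of proteins.
#' @param expression data frame with an `id` column and one or more
#'   fold-change columns.
#' @param column name of the fold-change column to rank on.
#' @param max_len length cutoff (strict: `length < max_len`).
#' @param require_sp require a positive [predict_signal_peptide()] call.
#' @param min_log2fc optional minimum fold-change (default `NULL`: rank
#'   only, no cut).
#' @return data frame: `id`, `species`, `length`, `log2fc`, `sp_call`,
#'   `rank` (1 = most induced).
#' @export
screen_short_secreted <- function(proteome, expression,
                                  column = "flg22_90min", max_len = 150L,
                                  require_sp = TRUE, min_log2fc = NULL) {
  stopifnot(inherits(proteome, "seq_set"))
  empty <- data.frame(id = character(), species = character(),
                      length = integer(), log2fc = numeric(),
                      sp_call = logical(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(proteome) == 0L) return(empty)
  if (!column %in% names(expression))
    stop("expression table has no column '", column, "'")
  len <- nchar(proteome$residues)
  keep <- len < max_len
  cand <- proteome[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  sp_call <- vapply(cand$residues,
                    function(s) !is.null(predict_signal_peptide(s)),
                    logical(1), USE.NAMES = FALSE)
  if (require_sp) {
    cand <- cand[sp_call, , drop = FALSE]
    sp_call <- sp_call[sp_call]
  }
  if (nrow(cand) == 0L) return(empty)
  fc <- expression[[column]][match(cand$id, expression$id)]
  if (anyNA(fc))
    warning("no expression row for: ",
            paste(cand$id[is.na(fc)], collapse = ", "),
            " (retained with NA fold-change, ranked last)")
  if (!is.null(min_log2fc)) {
    drop <- !is.na(fc) & fc < min_log2fc
    cand <- cand[!drop, , drop = FALSE]
    sp_call <- sp_call[!drop]
    fc <- fc[!drop]
  }
  ord <- order(is.na(fc), -ifelse(is.na(fc), -Inf, fc), cand$id)
  out <- data.frame(id = cand$id[ord], species = cand$species[ord],
                    length = nchar(cand$residues[ord]), log2fc = fc[ord],
                    sp_call = sp_call[ord], stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out
}
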