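# Cross-validated search for the final GRNN input subset.

#' Select the final GRNN input subset from the PLS shortlist
#'
#' Exhaustively scores every subset of the shortlist that contains the
#' primary descriptor `dft_nci`, up to `max_size` inputs (with a shortlist
#' of 10 and the default cap of 6 this is 382 candidate networks). Each
#' candidate is scored by its K-fold cross-validated RMSE at the best
#' smoothing factor on `grid` (see [optimize_sigma()]). The winner is the
#' candidate with the lowest CV RMSE; ties go first to the smaller subset,
#' then to lexicographic name order. The baseline single-input network
#' `["dft_nci"]` is always in the candidate pool, so the selected subset
#' never scores worse than the primary descriptor alone.
#'
#' @param shortlist Character vector of candidate descriptor names; must
#'   contain `"dft_nci"`.
#' @param train An [nci_dataset] with references.
#' @param cv A [cv_config()].
#' @param grid Sigma grid, as in [optimize_sigma()].
#' @param max_size Largest subset size to consider (default 6).
#' @param screening Optional `screening_result` (from [rank_descriptors()])
#'   to fill in; a bare result is created otherwise.
#' @return A `screening_result` with `final_subset`, `subset_scores`
#'   (data.frame of all scored candidates, best first, with their optimal
#'   sigma and CV RMSE in kcal/mol) and, as attribute-like fields,
#'   `best_sigma`, `best_oof` (out-of-fold predictions of the winner) and
#'   `best_sigma_table`.
#' @export
select_final_subset <- function(shortlist, train, cv,
                                grid = c(0.1, 2, 0.1), max_size = 6,
                                screening = NULL) {
  if (!"dft_nci" %in% shortlist) {
    abort("shortlist must contain the primary descriptor 'dft_nci'",
          "grnncorr_argument_error")
  }
  others <- setdiff(shortlist, "dft_nci")
  max_extra <- min(length(others), max(0, max_size - 1))
  candidates <- list(c("dft_nci"))
  for (m in seq_len(max_extra)) {
    combs <- utils::combn(others, m, simplify = FALSE)
    candidates <- c(candidates,
                    lapply(combs, function(s) c("dft_nci", s)))
  }

  scored <- vector("list", length(candidates))
  best <- NULL
  for (i in seq_along(candidates)) {
    subset_i <- candidates[[i]]
    opt <- optimize_sigma(train, subset_i, grid, cv)
    score <- min(opt$table$cv_rmse)
    scored[[i]] <- data.frame(
      subset = paste(subset_i, collapse = "+"),
      size = length(subset_i),
      sigma = opt$sigma,
      cv_rmse = score,
      stringsAsFactors = FALSE
    )
    key <- list(score, length(subset_i),
                paste(sort(subset_i), collapse = "\r"))
    better <- is.null(best) ||
      score < best$key[[1]] ||
      (score == best$key[[1]] &&
       (key[[2]] < best$key[[2]] ||
        (key[[2]] == best$key[[2]] && key[[3]] < best$key[[3]])))
    if (better) best <- list(key = key, subset = subset_i, opt = opt)
  }
  scores <- do.call(rbind, scored)
  scores <- scores[order(scores$cv_rmse, scores$size, scores$subset), ]
  rownames(scores) <- NULL

  out <- screening %||% structure(
    list(ranking = NULL, shortlist = shortlist,
         final_subset = NULL, subset_scores = NULL),
    class = "screening_result"
  )
  out$final_subset <- best$subset
  out$subset_scores <- scores
  out$best_sigma <- best$opt$sigma
  out$best_sigma_table <- best$opt$table
  out$best_oof <- best$opt$oof_pred
  out$best_obs <- best$opt$obs
  out
}
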