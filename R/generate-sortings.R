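#' Generate synthetic card-sortings and importance ratings
#'
#' Emulates the focus-group sorting exercise behind a concept map. A planted
#' partition of the statements into `n_true_clusters` clusters is drawn; each
#' participant piles every statement, with probability `sort_fidelity` into
#' the pile corresponding to its true cluster and otherwise into a uniformly
#' chosen other pile. Pile labels are permuted per participant (pile identity
#' is arbitrary, only co-membership matters). Each participant also rates
#' every statement on the 1-5 importance scale, drawn around the statement's
#' cluster-level mean and rounded/clipped to the integer scale.
#'
#' @param spec A [sorting_spec()].
#' @return A list with class `sorting_data`: `sortings` (long tibble:
#'   `participant_id`, `statement_id`, `pile_id`), `ratings` (long tibble:
#'   `participant_id`, `statement_id`, `rating` in 1-5), and `statements`
#'   (tibble: `statement_id`, `true_cluster`) recording the planted structure
#'   for recovery tests.
#' @examples
#' srt <- generate_sortings(sorting_spec(n_statements = 12, n_true_clusters = 3))
#' @export
generate_sortings <- function(spec) {
  if (!inherits(spec, "sorting_spec")) {
    stop_invalid("spec", "must be a sorting_spec")
  }
  withr::with_seed(spec$seed, {
    S <- spec$n_statements
    P <- spec$n_participants
    K <- spec$n_true_clusters
    true_cluster <- sort(rep_len(seq_len(K), S))
    statements <- tibble::tibble(
      statement_id = sprintf("S%03d", seq_len(S)),
      true_cluster = true_cluster
    )
    sortings <- vector("list", P)
    ratings <- vector("list", P)
    for (p in seq_len(P)) {
      keep <- runif(S) <= spec$sort_fidelity
      pile <- true_cluster
      if (any(!keep) && K > 1) {
        pile[!keep] <- vapply(true_cluster[!keep], function(k) {
          sample(setdiff(seq_len(K), k), 1)
        }, integer(1))
      }
      relabel <- sample(K) # participant-specific arbitrary pile labels
      sortings[[p]] <- tibble::tibble(
        participant_id = sprintf("FG%02d", p),
        statement_id = statements$statement_id,
        pile_id = relabel[pile]
      )
      latent <- rnorm(S, spec$rating_means[true_cluster], spec$rating_sd)
      ratings[[p]] <- tibble::tibble(
        participant_id = sprintf("FG%02d", p),
        statement_id = statements$statement_id,
        rating = as.integer(pmin(pmax(round(latent), 1), 5))
      )
    }
    structure(
      list(
        sortings = dplyr::bind_rows(sortings),
        ratings = dplyr::bind_rows(ratings),
        statements = statements,
        spec = spec
      ),
      class = "sorting_data"
    )
  })
}

#' @export
print.sorting_data <- function(x, ...) {
  cat(sprintf(
    "<sorting_data> %d statements sorted and rated by %d participants (%d planted clusters)\n",
    x$spec$n_statements, x$spec$n_participants, x$spec$n_true_clusters
  ))
  invisible(x)
}
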