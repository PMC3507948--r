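# Reciprocal-best-hit orthology calls from paired similarity hit tables.

rank_hits <- function(table, query_id) {
  h <- dplyr::filter(as_tibble(table), .data$query == query_id,
                     .data$subject != query_id)
  dplyr::arrange(h, dplyr::desc(.data$bitscore), .data$evalue, .data$subject)
}

#' Top-k hits of a query in a hit table
#'
#' Subjects ranked by descending bitscore, ties broken by ascending e-value
#' then ascending subject id; self-hits are excluded. A query absent from the
#' table yields an empty result.
#'
#' @param table A hit-table tibble (see [read_hit_table()]).
#' @param query_id Query id.
#' @param k Maximum number of subjects (>= 1).
#' @return Character vector of at most `k` subject ids, best first.
#' @export
top_hits <- function(table, query_id, k = 3L) {
  if (k < 1L) stop_domain("k must be >= 1")
  head(rank_hits(table, query_id)$subject, k)
}

#' Reciprocal-best-hit orthology calls
#'
#' For each species-A query: `strict` when the query and its best hit are
#' mutually rank 1; `relaxed` when some subject reciprocates within the top
#' `k` both ways (but not rank-1/rank-1); otherwise `absent`. `k = 1`
#' reproduces the strict-only definition.
#'
#' @param ab Hit table of species-A queries against species-B subjects.
#' @param ba Hit table of species-B queries against species-A subjects.
#' @param k Reciprocation depth for the relaxed call (default 3).
#' @return An `orthology_calls` tibble, one row per A-side query: `query`,
#'   `partner` (`NA` when absent), `status`
#'   (`"strict"`/`"relaxed"`/`"absent"`), `rank_ab`, `rank_ba`.
#' @export
reciprocal_best <- function(ab, ba, k = 3L) {
  if (k < 1L) stop_domain("k must be >= 1")
  a_ids <- union(unique(ab$query), unique(ba$subject))
  b_ids <- union(unique(ab$subject), unique(ba$query))
  clash <- intersect(a_ids, b_ids)
  if (length(clash)) {
    stop_domain("id(s) appear on both species sides: %s",
                paste(head(clash, 3), collapse = ", "))
  }
  calls <- purrr::map(sort(unique(ab$query)), function(q) {
    fwd <- head(rank_hits(ab, q)$subject, k)
    for (r_ab in seq_along(fwd)) {
      s <- fwd[r_ab]
      back <- head(rank_hits(ba, s)$subject, k)
      r_ba <- match(q, back)
      if (!is.na(r_ba)) {
        status <- if (r_ab == 1L && r_ba == 1L) "strict" else "relaxed"
        return(tibble(query = q, partner = s, status = status,
                      rank_ab = r_ab, rank_ba = r_ba))
      }
    }
    tibble(query = q, partner = NA_character_, status = "absent",
           rank_ab = NA_integer_, rank_ba = NA_integer_)
  })
  out <- dplyr::bind_rows(calls)
  structure(out, class = c("orthology_calls", class(out)), k = k)
}

#' Is a whole gene family absent from the partner proteome?
#'
#' A family (e.g. RGR/peropsin) is called absent iff every member's
#' reciprocal-best-hit call is absent; members without any call count as
#' absent.
#'
#' @param calls An `orthology_calls` tibble from [reciprocal_best()].
#' @param family_ids Ids of the family's A-side members.
#' @return `TRUE` when no family member has a reciprocating partner.
#' @export
family_absent <- function(calls, family_ids) {
  fam <- dplyr::filter(as_tibble(calls), .data$query %in% family_ids)
  nrow(fam) == 0L || all(fam$status == "absent")
}
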