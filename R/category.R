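#' Infer a restaurant's primary category from its review text
#'
#' Platforms assign businesses multiple unordered category terms; analyses
#' need a single primary category so each restaurant lands in at most one
#' choice set. The primary term is the assigned term occurring most often in
#' the business's review texts, counting case-insensitive whole-word
#' occurrences (multi-word terms matched as phrases). The umbrella term
#' "Restaurants" identifies restaurants but never competes as a category.
#'
#' Ties break by higher count, then earlier position in the assigned-terms
#' list, then lexicographically — deterministic and input-stable. A business
#' with no reviews (or only empty text) falls back to its first assigned
#' term with a warning; a business with no non-umbrella terms raises a
#' distinct `contextchoice_no_category` error.
#'
#' @param assigned_terms Character vector of the business's category terms.
#' @param review_texts Character vector of the business's review texts (may
#'   be empty).
#' @return A list with `primary_term` and `term_counts` (named integer).
#' @examples
#' infer_primary_category(
#'   c("Italian", "Pizza"),
#'   c("great pizza, will get pizza again", "best Pizza in town")
#' )
#' @export
infer_primary_category <- function(assigned_terms, review_texts) {
  terms <- assigned_terms[tolower(assigned_terms) != "restaurants"]
  if (length(terms) == 0) {
    stopf("business has no category terms besides the umbrella term.",
          class = "contextchoice_no_category")
  }
  texts <- review_texts[!is.na(review_texts) & nzchar(review_texts)]
  if (length(texts) == 0) {
    rlang::warn("no review text; falling back to first assigned term",
                class = "contextchoice_category_fallback")
    return(list(primary_term = terms[[1]],
                term_counts = setNames(rep(0L, length(terms)), terms)))
  }
  blob <- paste(texts, collapse = " \n ")
  counts <- vapply(terms, function(term) {
    pat <- paste0("\\b", gsub("\\s+", "\\\\s+",
                              stringr::str_escape(term)), "\\b")
    sum(stringr::str_count(blob, stringr::regex(pat, ignore_case = TRUE)))
  }, integer(1))
  ord <- order(-counts, seq_along(terms), terms)
  list(primary_term = terms[ord[1]], term_counts = counts)
}

#' Primary-category assignments for a business table
#'
#' Applies [infer_primary_category()] to every business, pooling that
#' business's review texts. Businesses without any non-umbrella term are
#' excluded and tallied in `attr(, "excluded")`; empty-text fallbacks are
#' counted in `attr(, "fallbacks")`.
#'
#' @param businesses Tibble with `business_id` and list-column
#'   `assigned_terms`.
#' @param reviews Review tibble with `business_id`, `text`.
#' @return Tibble of `business_id`, `primary_term`.
#' @export
infer_categories <- function(businesses, reviews) {
  texts <- split(reviews$text, reviews$business_id)
  excluded <- 0L
  fallbacks <- 0L
  rows <- purrr::map2(businesses$business_id, businesses$assigned_terms,
                      function(bid, terms) {
    res <- withCallingHandlers(
      tryCatch(
        infer_primary_category(terms, texts[[bid]] %||% character(0)),
        contextchoice_no_category = function(e) NULL
      ),
      contextchoice_category_fallback = function(w) {
        fallbacks <<- fallbacks + 1L
        invokeRestart("muffleWarning")
      }
    )
    if (is.null(res)) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    tibble::tibble(business_id = bid, primary_term = res$primary_term)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  attr(out, "fallbacks") <- fallbacks
  out
}
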