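#' Hickman vector of a contact network
#'
#' The Hickman vector of an N-cell embryo is a length-N descriptor whose
#' entry n (for 0 <= n < N) counts the blastomeres with exactly n cell
#' contacts: the degree distribution of the contact network. Entry 1 of the
#' returned R vector corresponds to n = 0.
#'
#' @param net A `contact_network`.
#' @return Integer vector of class `hickman_vector`, length `n_nodes`,
#'   summing to `n_nodes`.
#' @export
hickman_vector <- function(net) {
  if (!inherits(net, "contact_network")) {
    abort("`net` must be a contact_network", "invalid_parameter")
  }
  deg <- network_degrees(net)
  counts <- tabulate(deg + 1L, nbins = net$n_nodes)
  structure(as.integer(counts), class = "hickman_vector")
}

#' @export
print.hickman_vector <- function(x, ...) {
  cat(format_hickman(x), "\n")
  invisible(x)
}

#' Format a Hickman vector as the conventional bracket string
#'
#' @param hv Integer vector of degree counts.
#' @return A string such as `"[0, 0, 2, 2]"`.
#' @export
format_hickman <- function(hv) {
  paste0("[", paste(as.integer(hv), collapse = ", "), "]")
}

# Erdos-Gallai: is this non-negative integer sequence the degree sequence of
# some simple graph?
is_graphical_degrees <- function(deg) {
  deg <- sort(as.integer(deg), decreasing = TRUE)
  n <- length(deg)
  if (any(deg < 0) || any(deg > n - 1L)) return(FALSE)
  if (sum(deg) %% 2L != 0L) return(FALSE)
  for (k in seq_len(n)) {
    lhs <- sum(deg[seq_len(k)])
    rhs <- k * (k - 1L) + sum(pmin(deg[-seq_len(k)], k))
    if (lhs > rhs) return(FALSE)
  }
  TRUE
}

# Expand a Hickman count vector into the degree multiset it describes.
hickman_to_degrees <- function(hv) {
  rep.int(seq_along(hv) - 1L, as.integer(hv))
}

#' Is a count vector a valid Hickman vector?
#'
#' Valid means: length N with entries summing to N, even total degree, and a
#' degree multiset realizable by some simple graph (Erdos-Gallai condition).
#'
#' @param hv Integer vector of degree counts.
#' @return Logical scalar.
#' @export
is_valid_hickman <- function(hv) {
  hv <- as.integer(hv)
  n <- length(hv)
  if (n < 1L || anyNA(hv) || any(hv < 0L) || sum(hv) != n) return(FALSE)
  is_graphical_degrees(hickman_to_degrees(hv))
}

#' Mean number of cell contacts per blastomere
#'
#' The biomarker at the heart of the package: twice the number of contacts
#' divided by the number of blastomeres (the mean degree of the contact
#' network). Lies in [0, N-1] for an N-cell embryo.
#'
#' @param net A `contact_network`.
#' @return Numeric scalar.
#' @export
mean_contacts <- function(net) {
  if (!inherits(net, "contact_network")) {
    abort("`net` must be a contact_network", "invalid_parameter")
  }
  2 * nrow(net$edges) / net$n_nodes
}

# Table of named four-cell arrangements; everything else is "Other".
arrangement_table_4cell <- function() {
  list(
    "0,0,0,4" = "Tetrahedral",
    "0,0,2,2" = "Pseudotetrahedral",
    "0,0,4,0" = "Planar",
    "0,1,2,1" = "Closed Y",
    "0,2,2,0" = "Linear"
  )
}

#' Classify a four-cell arrangement from its Hickman vector
#'
#' Maps the five named four-cell arrangements to their nicknames:
#' `[0,0,0,4]` Tetrahedral (contact graph K4), `[0,0,2,2]` Pseudotetrahedral
#' (K4 minus an edge), `[0,0,4,0]` Planar (4-cycle), `[0,1,2,1]` Closed Y
#' (triangle plus pendant), `[0,2,2,0]` Linear (path). Any other graphical
#' vector is labelled `"Other"`.
#'
#' @param hv A length-4 Hickman vector (integer counts).
#' @return One of `"Tetrahedral"`, `"Pseudotetrahedral"`, `"Planar"`,
#'   `"Closed Y"`, `"Linear"`, `"Other"`.
#' @export
classify_arrangement_4cell <- function(hv) {
  hv <- as.integer(hv)
  if (length(hv) != 4L || !is_valid_hickman(hv)) {
    abort(sprintf("not a graphical length-4 Hickman vector: %s",
                  format_hickman(hv)), "invalid_vector")
  }
  key <- paste(hv, collapse = ",")
  hit <- arrangement_table_4cell()[[key]]
  if (is.null(hit)) "Other" else hit
}

#' Frequency distribution of Hickman vectors
#'
#' Tabulates the arrangements observed across a cohort of same-stage contact
#' networks, sorted by decreasing count with lexicographic vector tie-break.
#'
#' @param nets List of `contact_network` objects, all with the same number of
#'   nodes.
#' @return A data.frame with columns `vector` (bracket string), `count`, and
#'   (for 4-cell cohorts) `nickname`.
#' @export
arrangement_frequencies <- function(nets) {
  if (length(nets) == 0L) {
    return(data.frame(vector = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (!all(vapply(nets, inherits, logical(1), "contact_network"))) {
    abort("`nets` must be a list of contact_network objects", "invalid_input")
  }
  ns <- vapply(nets, `[[`, integer(1), "n_nodes")
  if (length(unique(ns)) != 1L) {
    abort("all networks must have the same number of nodes", "invalid_input")
  }
  n <- ns[1]
  hvs <- lapply(nets, hickman_vector)
  keys <- vapply(hvs, function(h) paste(sprintf("%02d", h), collapse = ","),
                 character(1))
  tab <- table(keys)
  ord <- order(-as.integer(tab), names(tab))
  keys_sorted <- names(tab)[ord]
  vecs <- lapply(strsplit(keys_sorted, ","), as.integer)
  out <- data.frame(
    vector = vapply(vecs, format_hickman, character(1)),
    count = as.integer(tab)[ord],
    stringsAsFactors = FALSE
  )
  if (n == 4L) {
    out$nickname <- vapply(vecs, classify_arrangement_4cell, character(1))
  }
  out
}

#' Enumerate all realizable Hickman vectors on n cells
#'
#' Returns every count vector realizable as the degree distribution of some
#' simple graph on n nodes, found by enumerating non-increasing degree
#' sequences and keeping the graphical ones (Erdos-Gallai). For n = 4 there
#' are 11; the count grows quickly with n, which is why no nickname taxonomy
#' exists beyond the four-cell stage.
#'
#' @param n Number of cells, between 1 and 8.
#' @return List of integer vectors (class `hickman_vector`), sorted
#'   lexicographically.
#' @export
enumerate_possible_vectors <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > 8L) {
    abort("`n` must be an integer in [1, 8]", "invalid_parameter")
  }
  # all non-increasing sequences of length n over 0..n-1
  seqs <- list(integer(0))
  for (i in seq_len(n)) {
    seqs <- unlist(lapply(seqs, function(s) {
      top <- if (length(s)) s[length(s)] else n - 1L
      lapply(0:top, function(d) c(s, d))
    }), recursive = FALSE)
  }
  keep <- Filter(is_graphical_degrees, seqs)
  counts <- unique(lapply(keep, function(d) tabulate(d + 1L, nbins = n)))
  keys <- vapply(counts, function(h) paste(sprintf("%02d", h), collapse = ","),
                 character(1))
  counts <- counts[order(keys)]
  lapply(counts, function(h) structure(as.integer(h), class = "hickman_vector"))
}
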