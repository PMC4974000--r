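# Humphrey 30-2 visual-field reliability screen and defect-cluster classifier.

P_CATEGORIES <- c(">=5%", "<5%", "<2%", "<1%", "<0.5%")
GHT_STATES <- c("within normal limits", "borderline", "outside normal limits",
                "general reduction", "abnormally high")

.vf_env <- new.env(parent = emptyenv())

#' The Humphrey 30-2 test-point grid
#'
#' Returns the packaged 30-2 pattern definition: 76 points on a 6-degree
#' lattice offset 3 degrees from the meridians, with edge membership (the
#' outermost ring, defined as points with fewer than eight lattice
#' neighbours inside the pattern) and the two blind-spot points
#' (x = +15, y = +/-3 for a right eye) marked explicitly, so the edge and
#' blind-spot definitions are data rather than code.
#'
#' @return A tibble with columns `x_deg`, `y_deg`, `is_edge`,
#'   `is_blind_spot`.
#' @export
vf_grid_30_2 <- function() {
  if (is.null(.vf_env$grid)) {
    path <- system.file("extdata", "grid_30_2.csv", package = "octroc",
                        mustWork = TRUE)
    .vf_env$grid <- readr::read_csv(path, show_col_types = FALSE,
                                    progress = FALSE)
  }
  .vf_env$grid
}

# Normalize the probability-category labels of a pattern deviation plot.
normalize_p_category <- function(x) {
  key <- gsub("\\s|%", "", tolower(as.character(x)))
  map <- c(">=5" = ">=5%", "ge5" = ">=5%", "5" = ">=5%",
           "<5" = "<5%", "lt5" = "<5%",
           "<2" = "<2%", "lt2" = "<2%",
           "<1" = "<1%", "lt1" = "<1%",
           "<0.5" = "<0.5%", "lt0.5" = "<0.5%")
  out <- unname(map[key])
  if (any(is.na(out) & !is.na(x))) {
    abort(paste0("unknown probability category: ",
                 paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", ")))
  }
  factor(out, levels = P_CATEGORIES, ordered = TRUE)
}

#' Visual-field test reliability
#'
#' A test is reliable when the fixation loss is < 20% and the false-positive
#' rate is < 33%, both strict.
#'
#' @param fixation_loss Fixation loss percentage(s) in \[0, 100\].
#' @param false_positive False-positive percentage(s) in \[0, 100\].
#' @return Logical vector.
#' @export
vf_reliable <- function(fixation_loss, false_positive) {
  if (any(fixation_loss < 0 | fixation_loss > 100 |
            false_positive < 0 | false_positive > 100, na.rm = TRUE)) {
    abort("reliability indices must be percentages in [0, 100]")
  }
  fixation_loss < 20 & false_positive < 33
}

#' Find glaucomatous defect clusters on a pattern deviation plot
#'
#' Identifies maximal clusters of >= 3 contiguous non-edge points depressed
#' at p < 5%, of which at least one point is depressed at p < 1%.
#' Contiguity is 8-neighbourhood on the 6-degree lattice; by default a
#' cluster may not span the horizontal midline (both conventions the
#' instrument literature uses are configurable). Edge-ring and blind-spot
#' points never participate.
#'
#' @param pd A tibble with columns `x_deg`, `y_deg`, `p_category` (one of
#'   `">=5%"`, `"<5%"`, `"<2%"`, `"<1%"`, `"<0.5%"`). Points omitted from
#'   the table are treated as not depressed.
#' @param grid The 30-2 grid definition, see [vf_grid_30_2()].
#' @param span_midline If `FALSE` (default) clusters must lie within one
#'   hemifield.
#' @return A tibble of the points belonging to qualifying clusters, with a
#'   `cluster` id column; zero rows when no cluster qualifies.
#' @export
vf_defect_clusters <- function(pd, grid = vf_grid_30_2(),
                               span_midline = FALSE) {
  stopifnot(is.data.frame(pd),
            all(c("x_deg", "y_deg", "p_category") %in% names(pd)))
  gkey <- paste(grid$x_deg, grid$y_deg)
  pkey <- paste(pd$x_deg, pd$y_deg)
  unknown <- !pkey %in% gkey
  if (any(unknown)) {
    abort(paste0("point(s) not on the 30-2 grid: ",
                 paste(unique(pkey[unknown]), collapse = "; ")))
  }
  if (anyDuplicated(pkey)) abort("duplicate grid points in pattern deviation map")
  pd <- tibble::as_tibble(pd)
  pd$p_category <- normalize_p_category(pd$p_category)
  meta <- grid[match(pkey, gkey), c("is_edge", "is_blind_spot")]
  depressed <- pd$p_category >= "<5%"   # ordered factor: <5%, <2%, <1%, <0.5%
  eligible <- which(depressed & !meta$is_edge & !meta$is_blind_spot)
  if (length(eligible) < 3L) {
    return(empty_cluster_table())
  }
  x <- pd$x_deg[eligible]; y <- pd$y_deg[eligible]
  n <- length(eligible)
  adj <- function(i, j) {
    touch <- abs(x[i] - x[j]) <= 6 & abs(y[i] - y[j]) <= 6 & i != j
    if (!span_midline) touch <- touch & sign(y[i]) == sign(y[j])
    touch
  }
  # union-find over at most 74 candidate points
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (adj(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- integer(0); cluster_id <- integer(0); next_id <- 0L
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    cats <- pd$p_category[eligible[members]]
    if (length(members) >= 3L && any(cats >= "<1%")) {
      next_id <- next_id + 1L
      keep <- c(keep, eligible[members])
      cluster_id <- c(cluster_id, rep(next_id, length(members)))
    }
  }
  if (!length(keep)) return(empty_cluster_table())
  out <- pd[keep, c("x_deg", "y_deg", "p_category")]
  out$cluster <- cluster_id
  out[order(out$cluster, -out$y_deg, out$x_deg), ]
}

empty_cluster_table <- function() {
  tibble::tibble(x_deg = numeric(0), y_deg = numeric(0),
                 p_category = factor(character(0), levels = P_CATEGORIES,
                                     ordered = TRUE),
                 cluster = integer(0))
}

#' Classify a visual field as glaucomatous
#'
#' A field is glaucomatous when the pattern deviation plot contains a
#' qualifying defect cluster (see [vf_defect_clusters()]) or the glaucoma
#' hemifield test is outside normal limits.
#'
#' @param pd Pattern deviation map, as for [vf_defect_clusters()]; may have
#'   zero rows.
#' @param ght Glaucoma hemifield test result, one of `r toString(GHT_STATES)`.
#' @param grid The 30-2 grid definition.
#' @param span_midline Passed to [vf_defect_clusters()].
#' @return Logical scalar.
#' @export
vf_classify_glaucomatous <- function(pd, ght = "within normal limits",
                                     grid = vf_grid_30_2(),
                                     span_midline = FALSE) {
  ght <- match.arg(ght, GHT_STATES)
  has_cluster <- nrow(vf_defect_clusters(pd, grid, span_midline)) > 0L
  has_cluster || ght == "outside normal limits"
}

#' Confirm a glaucomatous visual-field defect across repeated tests
#'
#' A defect is confirmed when at least two reliable examinations each
#' classify the field as glaucomatous.
#'
#' @param tests A tibble with one row per examination and columns `defect`
#'   (logical classification) plus either `reliable` (logical) or
#'   `fixation_loss` and `false_positive` percentages from which reliability
#'   is derived via [vf_reliable()].
#' @return Logical scalar.
#' @export
vf_confirmed_defect <- function(tests) {
  stopifnot(is.data.frame(tests), "defect" %in% names(tests))
  if (nrow(tests) == 0L) abort("at least one examination required")
  reliable <- if ("reliable" %in% names(tests)) {
    as.logical(tests$reliable)
  } else {
    vf_reliable(tests$fixation_loss, tests$false_positive)
  }
  sum(reliable & as.logical(tests$defect), na.rm = TRUE) >= 2L
}
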