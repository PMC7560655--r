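check_svs <- function(svs) {
  stopifnot(all(c("chrom_a", "pos_a", "chrom_b", "pos_b", "type") %in% names(svs)))
  stopifnot(all(svs$pos_a >= 1), all(svs$pos_b >= 1))
  invisible(svs)
}

#' Match structural-variant breakpoints to copy-alteration boundaries
#'
#' Pairs every SV breakpoint with every copy-number alteration boundary
#' on the same chromosome lying within `window` bp (inclusive; 5 kb by
#' default), the rule used to rescue rearrangements with copy-number
#' support.
#'
#' @param svs Tibble of SVs: `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `type` (single sample).
#' @param boundaries Tibble of alteration boundaries: `alteration`,
#'   `chrom`, `pos`.
#' @param window Maximum breakpoint-boundary distance in bp.
#' @return Tibble of matches: `sv_id`, `breakpoint` ("A"/"B"), `chrom`,
#'   `pos`, `alteration`, `boundary_pos`, `distance`.
#' @export
match_sv_to_cna <- function(svs, boundaries, window = 5000) {
  check_svs(svs)
  stopifnot(all(c("alteration", "chrom", "pos") %in% names(boundaries)))
  bps <- sv_breakpoints(svs)
  bps |>
    inner_join(boundaries |> rename(boundary_pos = "pos"), by = "chrom",
               relationship = "many-to-many") |>
    mutate(distance = abs(.data$pos - .data$boundary_pos)) |>
    filter(.data$distance <= window) |>
    select("sv_id", "breakpoint", "chrom", "pos", "alteration", "boundary_pos", "distance")
}

sv_breakpoints <- function(svs) {
  svs <- svs |> mutate(sv_id = row_number())
  bind_rows(
    svs |> select("sv_id", chrom = "chrom_a", pos = "pos_a") |> mutate(breakpoint = "A"),
    svs |> select("sv_id", chrom = "chrom_b", pos = "pos_b") |> mutate(breakpoint = "B")
  )
}

#' Classify t(11;17) hotspot translocations
#'
#' A translocation is positive when one breakpoint falls on chromosome
#' 17q at 30 Mb or higher and the other on chromosome 11q between 60 and
#' 80 Mb (GRCh37; bounds inclusive). Symmetric in breakpoint order;
#' non-translocation records return `FALSE` with a warning.
#'
#' @param svs Tibble of SV records (see [match_sv_to_cna()]).
#' @return Logical vector, one element per record.
#' @export
classify_t11_17 <- function(svs) {
  check_svs(svs)
  non_tr <- svs$type != "translocation"
  if (any(non_tr)) {
    warn(sprintf("%d non-translocation record(s) classified FALSE", sum(non_tr)))
  }
  side17 <- function(chrom, pos) chrom == "17" & pos >= 30e6
  side11 <- function(chrom, pos) chrom == "11" & pos >= 60e6 & pos <= 80e6
  hit <- (side17(svs$chrom_a, svs$pos_a) & side11(svs$chrom_b, svs$pos_b)) |
    (side17(svs$chrom_b, svs$pos_b) & side11(svs$chrom_a, svs$pos_a))
  hit & !non_tr
}

#' Build the SV linkage graph over a sample's copy alterations
#'
#' Two copy alterations (or translocation events) are non-independent
#' when a structural variant joins them directly — one breakpoint within
#' `window` bp (5 kb) of each alteration's boundary — or when a chain of
#' SVs joins them through intervening chromosome sequences with
#' consecutive breakpoints at most `max_hop` bp (15 Mb) apart on the same
#' chromosome. Linkage is transitive: alterations are linked when any
#' path connects them. SNVs and indels are never nodes (rows of
#' `boundaries` with `class` `"snv"` or `"indel"` are dropped): point
#' mutations are always treated as independent of all other events.
#'
#' @param svs Single-sample SV tibble.
#' @param boundaries Tibble `alteration`, `chrom`, `pos` (one row per
#'   boundary; an alteration may have several), optional `class`.
#' @param window Breakpoint-to-boundary match distance, bp (inclusive).
#' @param max_hop Maximum same-chromosome gap between chained
#'   breakpoints, bp (inclusive).
#' @return A `linkage_graph`: the underlying igraph plus the alteration
#'   ids. Query with [independent_pair_filter()] or [linked_pairs()].
#' @export
build_linkage_graph <- function(svs, boundaries, window = 5000, max_hop = 15e6) {
  check_svs(svs)
  if ("class" %in% names(boundaries)) {
    boundaries <- boundaries |> filter(!.data$class %in% c("snv", "indel"))
  }
  alt_ids <- unique(boundaries$alteration)
  bps <- sv_breakpoints(svs) |> mutate(node = paste0("bp", .data$sv_id, .data$breakpoint))

  edges <- list()
  if (nrow(svs) > 0) {
    edges$sv <- tibble(from = paste0("bp", seq_len(nrow(svs)), "A"),
                       to   = paste0("bp", seq_len(nrow(svs)), "B"))
    # chain hops: breakpoints on the same chromosome within max_hop
    hop <- bps |>
      inner_join(bps, by = "chrom", suffix = c("", ".y"), relationship = "many-to-many") |>
      filter(.data$node < .data$node.y, abs(.data$pos - .data$pos.y) <= max_hop)
    edges$hop <- hop |> select(from = "node", to = "node.y")
    # boundary matches: alteration node to breakpoint node within window
    mt <- bps |>
      inner_join(boundaries |> rename(bpos = "pos"), by = "chrom",
                 relationship = "many-to-many") |>
      filter(abs(.data$pos - .data$bpos) <= window)
    edges$boundary <- mt |> select(from = "alteration", to = "node")
  }
  edge_df <- bind_rows(edges)
  if (!"from" %in% names(edge_df)) edge_df <- tibble(from = character(0), to = character(0))
  vertices <- tibble(name = unique(c(alt_ids, bps$node,
                                     edge_df$from, edge_df$to)))
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = vertices)
  structure(list(graph = g, alterations = alt_ids,
                 sample = if ("sample" %in% names(svs) && nrow(svs) > 0) svs$sample[1]
                          else NA_character_),
            class = "linkage_graph")
}

#' @export
print.linkage_graph <- function(x, ...) {
  cat("<linkage_graph>", length(x$alterations), "alterations,",
      igraph::gsize(x$graph), "edges\n")
  invisible(x)
}

#' Decide whether an alteration pair is independent or SV-linked
#'
#' @param graph A [build_linkage_graph()] result.
#' @param a,b Alteration identifiers.
#' @return `"linked"` when any SV path connects the pair, else
#'   `"independent"`.
#' @export
independent_pair_filter <- function(graph, a, b) {
  stopifnot(inherits(graph, "linkage_graph"))
  if (!all(c(a, b) %in% graph$alterations)) {
    abort(sprintf("unknown alteration id: %s",
                  paste(setdiff(c(a, b), graph$alterations), collapse = ", ")))
  }
  comp <- igraph::components(graph$graph)$membership
  if (comp[[a]] == comp[[b]]) "linked" else "independent"
}

#' All linked alteration pairs of a linkage graph
#'
#' @param graph A `linkage_graph`.
#' @return Tibble `alt_a`, `alt_b` (alt_a < alt_b), one row per linked
#'   pair, with the graph's `sample` id.
#' @export
linked_pairs <- function(graph) {
  stopifnot(inherits(graph, "linkage_graph"))
  alts <- graph$alterations
  if (length(alts) < 2) {
    return(tibble(sample = character(0), alt_a = character(0), alt_b = character(0)))
  }
  comp <- igraph::components(graph$graph)$membership[alts]
  pairs <- utils::combn(sort(alts), 2)
  linked <- comp[pairs[1, ]] == comp[pairs[2, ]]
  tibble(sample = graph$sample, alt_a = pairs[1, linked], alt_b = pairs[2, linked])
}

#' Linked alteration pairs for every sample of a cohort
#'
#' @param svs Multi-sample SV tibble (with `sample`).
#' @param boundaries Multi-sample boundary tibble (with `sample`).
#' @inheritParams build_linkage_graph
#' @return Tibble `sample`, `alt_a`, `alt_b`.
#' @export
linked_pairs_by_sample <- function(svs, boundaries, window = 5000, max_hop = 15e6) {
  samples <- union(unique(svs$sample), unique(boundaries$sample))
  map(samples, function(s) {
    g <- build_linkage_graph(svs |> filter(.data$sample == s),
                             boundaries |> filter(.data$sample == s),
                             window = window, max_hop = max_hop)
    linked_pairs(g) |> mutate(sample = s)
  }) |> list_rbind()
}
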