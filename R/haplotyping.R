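# Haplotype collapse, marker-based naming, minimum-spanning networks, and
# regional amplification summaries.

#' Collapse equal-length barcode records into haplotypes
#'
#' Exact-sequence deduplication. Records containing IUPAC ambiguity codes
#' or gaps cannot be assigned to a distinct haplotype and are reported
#' separately rather than forced. Haplotypes are ordered by first-seen
#' member id, which makes downstream naming deterministic.
#'
#' @param records trimmed panel data.frame, all residues equal length
#'   (run \code{\link{trim_to_common_region}} first if needed).
#' @return list(haplotypes = list of haplotype objects (name temporarily
#'   "", sequence, member_ids, countries), unassignable = character ids).
#' @export
collapse_haplotypes <- function(records) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  lens <- unique(nchar(records$residues))
  if (length(lens) != 1L) {
    stop("ragged input: trim records to a common region first",
         call. = FALSE)
  }
  clean <- !grepl("[^ACGT]", records$residues)
  unassignable <- records$id[!clean]
  rec <- records[clean, , drop = FALSE]
  haps <- list()
  index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(rec))) {
    s <- rec$residues[i]
    k <- get0(s, envir = index, ifnotfound = NA_integer_)
    if (is.na(k)) {
      k <- length(haps) + 1L
      assign(s, k, envir = index)
      haps[[k]] <- list(name = "", sequence = s,
                        member_ids = character(), countries = character())
    }
    haps[[k]]$member_ids <- c(haps[[k]]$member_ids, rec$id[i])
    ctry <- if ("country" %in% names(rec)) rec$country[i] else NA_character_
    if (!is.na(ctry)) {
      haps[[k]]$countries <- union(haps[[k]]$countries, ctry)
    }
  }
  list(haplotypes = haps, unassignable = unassignable)
}

#' Read a haplotype marker table
#'
#' TSV with columns haplotype, position, base: the diagnostic nucleotide
#' markers distinguishing named haplotypes within the trimmed region.
#' Published marker sets live in supplementary material and must be
#' transcribed by the user; the package hard-codes none.
#'
#' @param path TSV file.
#' @return data.frame(haplotype, position, base).
#' @export
read_marker_table <- function(path) {
  mt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("haplotype", "position", "base")
  if (!all(need %in% names(mt))) {
    stop("marker table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mt$position <- as.integer(mt$position)
  mt$base <- toupper(mt$base)
  mt
}

#' Assign names to collapsed haplotypes against a marker table
#'
#' A haplotype receives a known name iff it matches that name's full marker
#' set; matching two marker sets means the table is not discriminating and
#' is an error. Unmatched haplotypes get fresh names continuing the
#' numbering (H<k+1>, ...) in order of first observation. With an empty
#' marker table all haplotypes are novel and named H1..Hk.
#'
#' @param haps list of haplotypes from \code{\link{collapse_haplotypes}}.
#' @param markers data.frame(haplotype, position, base) or NULL; positions
#'   are 1-based within the trimmed region.
#' @return list(haplotypes = named haplotype list, novel = character vector
#'   of freshly assigned names).
#' @export
assign_haplotype_names <- function(haps, markers = NULL) {
  if (is.list(haps) && !is.null(haps$haplotypes)) haps <- haps$haplotypes
  if (length(haps) == 0L) return(list(haplotypes = haps, novel = character()))
  known <- character(0)
  if (!is.null(markers) && nrow(markers) > 0L) {
    seqlen <- nchar(haps[[1]]$sequence)
    if (any(markers$position < 1L | markers$position > seqlen)) {
      stop("marker positions outside the trimmed region (1-", seqlen, ")",
           call. = FALSE)
    }
    known <- unique(markers$haplotype)
  }
  next_num <- if (length(known)) {
    nums <- suppressWarnings(as.integer(sub("^H", "", known)))
    max(nums, 0L, na.rm = TRUE) + 1L
  } else 1L
  novel <- character()
  for (k in seq_along(haps)) {
    s <- split_chars(haps[[k]]$sequence)
    hits <- character()
    for (nm in known) {
      m <- markers[markers$haplotype == nm, , drop = FALSE]
      if (all(s[m$position] == m$base)) hits <- c(hits, nm)
    }
    if (length(hits) > 1L) {
      stop("haplotype with members ",
           paste(haps[[k]]$member_ids, collapse = ","),
           " matches multiple marker sets (", paste(hits, collapse = ","),
           "): marker table is not discriminating", call. = FALSE)
    }
    if (length(hits) == 1L) {
      haps[[k]]$name <- hits
    } else {
      haps[[k]]$name <- paste0("H", next_num)
      novel <- c(novel, haps[[k]]$name)
      next_num <- next_num + 1L
    }
  }
  dup <- duplicated(vapply(haps, `[[`, "", "name"))
  if (any(dup)) {
    stop("two distinct haplotypes received the same name; marker table ",
         "does not separate them", call. = FALSE)
  }
  list(haplotypes = haps, novel = novel)
}

hamming <- function(a, b) {
  sum(split_chars(a) != split_chars(b))
}

#' Minimum-spanning haplotype network
#'
#' Builds the minimum spanning tree over pairwise Hamming distances between
#' haplotype sequences (Kruskal's algorithm; edges sorted by weight then
#' lexicographic (name_i, name_j), giving a documented deterministic
#' tie-break). At typical intraspecific barcode distances the MST
#' reproduces the topology class of published haplotype networks.
#'
#' @param haps named haplotype list (from
#'   \code{\link{assign_haplotype_names}}, or a \code{collapse_haplotypes}
#'   result whose haplotypes already carry names).
#' @return a \code{haplotype_network}: nodes data.frame (name, n_members,
#'   countries), edges data.frame (from, to, weight), total_weight.
#' @export
haplotype_network <- function(haps) {
  if (is.list(haps) && !is.null(haps$haplotypes)) haps <- haps$haplotypes
  if (length(haps) == 0L) stop("no haplotypes", call. = FALSE)
  names_ <- vapply(haps, `[[`, "", "name")
  if (any(!nzchar(names_))) {
    names_ <- paste0("H", seq_along(haps))
  }
  nodes <- data.frame(
    name = names_,
    n_members = vapply(haps, function(h) length(h$member_ids), integer(1)),
    countries = vapply(haps, function(h)
      paste(sort(h$countries), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  n <- length(haps)
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (n > 1L) {
    cmb <- utils::combn(n, 2)
    all_edges <- data.frame(
      from = names_[cmb[1, ]], to = names_[cmb[2, ]],
      weight = apply(cmb, 2, function(ij) {
        hamming(haps[[ij[1]]]$sequence, haps[[ij[2]]]$sequence)
      }), stringsAsFactors = FALSE)
    # canonical edge naming: from < to lexicographically
    swap <- all_edges$from > all_edges$to
    tmp <- all_edges$from[swap]
    all_edges$from[swap] <- all_edges$to[swap]
    all_edges$to[swap] <- tmp
    all_edges <- all_edges[order(all_edges$weight, all_edges$from,
                                 all_edges$to), , drop = FALSE]
    # Kruskal with union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    idx <- stats::setNames(seq_len(n), names_)
    keep <- logical(nrow(all_edges))
    for (e in seq_len(nrow(all_edges))) {
      a <- find(idx[[all_edges$from[e]]])
      b <- find(idx[[all_edges$to[e]]])
      if (a != b) { parent[a] <- b; keep[e] <- TRUE }
    }
    edges <- all_edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges,
                 total_weight = sum(edges$weight)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges, total weight %g\n",
              nrow(x$nodes), nrow(x$edges), x$total_weight))
  invisible(x)
}

#' Per-region amplification summary for a primer pair
#'
#' "Matched" means a PERFECT call: zero mismatches and zero ambiguities
#' over both primer footprints. PROBABLE calls are tallied separately,
#' never counted as matched. Records without region metadata are listed
#' under "unknown", not dropped. Percentages are reported to one decimal.
#'
#' @param records panel data.frame with region_group (or country) metadata.
#' @param pair \code{primer_pair}.
#' @param thresholds \code{\link{screen_thresholds}}.
#' @param by metadata column to group by (default "region_group", falling
#'   back to "country" when absent).
#' @return data.frame: region, n, n_perfect, pct_perfect, n_probable; final
#'   row "overall" aggregates all records.
#' @export
regional_match_summary <- function(records, pair,
                                   thresholds = screen_thresholds(),
                                   by = NULL) {
  if (is.null(by)) {
    by <- if ("region_group" %in% names(records) &&
              !all(is.na(records$region_group))) "region_group" else
                "country"
  }
  if (!by %in% names(records)) {
    stop("no '", by, "' column in the panel", call. = FALSE)
  }
  rep_ <- screen_panel(pair, records, thresholds)
  region <- records[[by]]
  region[is.na(region) | !nzchar(region)] <- "unknown"
  calls <- rep_$calls
  grp <- split(seq_len(nrow(calls)), region)
  rows <- lapply(names(grp), function(g) {
    idx <- grp[[g]]
    np <- sum(calls$category[idx] == "PERFECT")
    data.frame(region = g, n = length(idx), n_perfect = np,
               pct_perfect = round(100 * np / length(idx), 1),
               n_probable = sum(calls$category[idx] == "PROBABLE"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region), , drop = FALSE]
  np <- sum(calls$category == "PERFECT")
  out <- rbind(out, data.frame(
    region = "overall", n = nrow(calls), n_perfect = np,
    pct_perfect = round(100 * np / nrow(calls), 1),
    n_probable = sum(calls$category == "PROBABLE"),
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
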