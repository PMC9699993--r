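#' Read a restriction-fragment map with bait annotations
#'
#' Reads the tab-delimited fragment-map dialect: the rmap file has four
#' headerless columns (chrom, start, end, fragment id) and the baitmap
#' five (chrom, start, end, fragment id, bait name). Coordinates are
#' 1-based inclusive. Fragments must be unique by id and, within a
#' chromosome, sorted, non-overlapping and contiguous (each start is the
#' previous end + 1); violations are reported with line numbers. Every
#' bait id must resolve in the rmap.
#'
#' @param rmap_path Path to the rmap TSV.
#' @param baitmap_path Path to the baitmap TSV.
#' @return A `chic_fragment_map`: list with `fragments` (tibble `chrom`,
#'   `start`, `end`, `fragment_id`, `midpoint`, `is_bait`, `bait_name`)
#'   and `bait_ids`.
#' @export
read_fragment_map <- function(rmap_path, baitmap_path) {
  rmap <- readr::read_tsv(rmap_path,
                          col_names = c("chrom", "start", "end", "fragment_id"),
                          col_types = "ciii", progress = FALSE)
  baitmap <- readr::read_tsv(baitmap_path,
                             col_names = c("chrom", "start", "end",
                                           "fragment_id", "bait_name"),
                             col_types = "ciiic", progress = FALSE)
  dup <- rmap$fragment_id[duplicated(rmap$fragment_id)]
  if (length(dup) > 0) {
    stop("duplicate fragment id(s) in rmap: ", paste(unique(dup), collapse = ", "),
         " (line ", which(duplicated(rmap$fragment_id))[1], ")", call. = FALSE)
  }
  # contiguity within chromosome, in file order
  for (ch in unique(rmap$chrom)) {
    sub <- rmap[rmap$chrom == ch, ]
    lines <- which(rmap$chrom == ch)
    if (is.unsorted(sub$start)) {
      stop("rmap fragments not sorted on ", ch, " (line ",
           lines[which(diff(sub$start) < 0)[1] + 1], ")", call. = FALSE)
    }
    bad <- which(sub$start[-1] != sub$end[-nrow(sub)] + 1)
    if (length(bad) > 0) {
      stop("rmap fragments not contiguous on ", ch, " (line ",
           lines[bad[1] + 1], ")", call. = FALSE)
    }
  }
  missing <- setdiff(baitmap$fragment_id, rmap$fragment_id)
  if (length(missing) > 0) {
    stop("baitmap id(s) absent from rmap: ",
         paste(missing, collapse = ", "), " (line ",
         which(baitmap$fragment_id %in% missing)[1], ")", call. = FALSE)
  }
  fragments <- rmap |>
    dplyr::mutate(
      midpoint = (.data$start + .data$end) / 2,
      is_bait = .data$fragment_id %in% baitmap$fragment_id) |>
    dplyr::left_join(baitmap |> dplyr::select("fragment_id", "bait_name"),
                     by = "fragment_id")
  structure(list(fragments = fragments, bait_ids = sort(baitmap$fragment_id)),
            class = "chic_fragment_map")
}

#' @export
print.chic_fragment_map <- function(x, ...) {
  cat("<chic_fragment_map>", nrow(x$fragments), "fragments,",
      length(x$bait_ids), "baits,",
      dplyr::n_distinct(x$fragments$chrom), "chromosome(s)\n")
  invisible(x)
}

#' Write a fragment map back to the rmap/baitmap dialect
#'
#' @param map A `chic_fragment_map`.
#' @param rmap_path,baitmap_path Output paths.
#' @return Invisibly, the map.
#' @export
write_fragment_map <- function(map, rmap_path, baitmap_path) {
  readr::write_tsv(map$fragments |>
                     dplyr::select("chrom", "start", "end", "fragment_id"),
                   rmap_path, col_names = FALSE)
  readr::write_tsv(map$fragments |>
                     dplyr::filter(.data$is_bait) |>
                     dplyr::mutate(bait_name = dplyr::coalesce(
                       .data$bait_name, paste0("bait_", .data$fragment_id))) |>
                     dplyr::select("chrom", "start", "end", "fragment_id",
                                   "bait_name"),
                   baitmap_path, col_names = FALSE)
  invisible(map)
}

#' Genomic distance between two fragments
#'
#' Midpoint-to-midpoint distance in bp; `NA` for trans (different
#' chromosome) pairs.
#'
#' @param map A `chic_fragment_map`.
#' @param bait_id,other_id Fragment id vectors.
#' @return Non-negative distances in bp, `NA` for trans pairs.
#' @export
pair_distance <- function(map, bait_id, other_id) {
  fr <- map$fragments
  i <- match(bait_id, fr$fragment_id)
  j <- match(other_id, fr$fragment_id)
  ifelse(fr$chrom[i] == fr$chrom[j],
         abs(fr$midpoint[i] - fr$midpoint[j]), NA_real_)
}

#' Read a pairwise count table
#'
#' Reads the chinput-like dialect: tab-delimited columns baitID,
#' otherEndID, N (read count), otherEndLen, distSign (signed bp distance,
#' empty or NA for trans pairs); lines starting with `#` are comments.
#' Distances are validated against the fragment map (midpoint-based,
#' within 1 bp); the sign of distSign is discarded — distances are
#' unsigned internally.
#'
#' @param path Path to the count TSV.
#' @param map A `chic_fragment_map` for validation.
#' @param replicate_id Label attached to the table.
#' @return Interaction tibble `bait_id`, `other_id`, `count`,
#'   `distance_bp` (`NA` = trans) with attribute `replicate_id`.
#' @export
read_interactions <- function(path, map, replicate_id = basename(path)) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_names = c("baitID", "otherEndID", "N",
                                       "otherEndLen", "distSign"),
                         col_types = "iiiid", progress = FALSE,
                         na = c("", "NA"))
  if (nrow(raw) == 0) stop("no records in ", path, call. = FALSE)
  if (any(raw$N < 0)) {
    stop("negative count at line ", which(raw$N < 0)[1], " of ", path,
         call. = FALSE)
  }
  known <- map$fragments$fragment_id
  bad <- which(!(raw$baitID %in% known) | !(raw$otherEndID %in% known))
  if (length(bad) > 0) {
    stop("unknown fragment id at line ", bad[1], " of ", path, call. = FALSE)
  }
  if (any(!(raw$baitID %in% map$bait_ids))) {
    stop("baitID not annotated as bait at line ",
         which(!(raw$baitID %in% map$bait_ids))[1], " of ", path, call. = FALSE)
  }
  d_map <- pair_distance(map, raw$baitID, raw$otherEndID)
  d_file <- abs(raw$distSign)
  mismatch <- which(!is.na(d_file) & !is.na(d_map) & abs(d_file - d_map) > 1)
  if (length(mismatch) > 0) {
    stop("distSign disagrees with map-derived distance by > 1 bp at line ",
         mismatch[1], " of ", path, call. = FALSE)
  }
  both_na <- is.na(d_file) & is.na(d_map)
  if (any(is.na(d_file) != is.na(d_map))) {
    stop("cis/trans flag disagrees with the map at line ",
         which(is.na(d_file) != is.na(d_map))[1], " of ", path, call. = FALSE)
  }
  out <- tibble::tibble(bait_id = raw$baitID, other_id = raw$otherEndID,
                        count = raw$N, distance_bp = d_map)
  attr(out, "replicate_id") <- replicate_id
  out
}

#' Write an interaction table in the chinput-like dialect
#'
#' @param interactions Interaction tibble (`bait_id`, `other_id`, `count`,
#'   `distance_bp`).
#' @param map A `chic_fragment_map` (for other-end lengths).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_interactions <- function(interactions, map, path) {
  fr <- map$fragments
  len <- fr$end - fr$start + 1
  out <- tibble::tibble(
    baitID = interactions$bait_id,
    otherEndID = interactions$other_id,
    N = interactions$count,
    otherEndLen = len[match(interactions$other_id, fr$fragment_id)],
    distSign = interactions$distance_bp
  )
  writeLines("# baitID\totherEndID\tN\totherEndLen\tdistSign", path)
  readr::write_tsv(out, path, col_names = FALSE, append = TRUE, na = "NA")
  invisible(path)
}

#' Write scored interactions
#'
#' Tabular dialect: one row per directed pair with `log_p`, `weight` and
#' `score` at 6 significant digits. Bed-pair dialect: both anchors'
#' 0-based half-open coordinates with the score in the score column.
#'
#' @param scored A `chic_scored` tibble.
#' @param path Output path.
#' @param format `"tabular"` or `"bed-pair"`.
#' @param map A `chic_fragment_map`; required for `"bed-pair"`.
#' @return Invisibly, the path.
#' @export
write_scored_interactions <- function(scored, path,
                                      format = c("tabular", "bed-pair"),
                                      map = NULL) {
  format <- match.arg(format)
  if (format == "tabular") {
    out <- scored |>
      dplyr::transmute(.data$bait_id, .data$other_id,
                       distance_bp = .data$distance_bp, count = .data$count,
                       log_p = sprintf("%#.6g", .data$log_p),
                       weight = sprintf("%#.6g", .data$weight),
                       score = sprintf("%#.6g", .data$score))
    readr::write_tsv(out, path)
  } else {
    if (is.null(map)) stop("`map` required for bed-pair output", call. = FALSE)
    fr <- map$fragments
    i <- match(scored$bait_id, fr$fragment_id)
    j <- match(scored$other_id, fr$fragment_id)
    out <- tibble::tibble(
      chrom1 = fr$chrom[i], start1 = fr$start[i] - 1L, end1 = fr$end[i],
      chrom2 = fr$chrom[j], start2 = fr$start[j] - 1L, end2 = fr$end[j],
      name = paste0(scored$bait_id, "_", scored$other_id),
      score = signif(scored$score, 6))
    readr::write_tsv(out, path)
  }
  invisible(path)
}

#' Read scored interactions written in the tabular dialect
#'
#' @param path Path written by [write_scored_interactions()].
#' @return Tibble with the tabular columns.
#' @export
read_scored_interactions <- function(path) {
  readr::read_tsv(path, col_types = "iididdd", progress = FALSE)
}
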