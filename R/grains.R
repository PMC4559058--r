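#' Pairwise great-circle distances between samples (km)
#'
#' Haversine distances on a sphere of radius 6371 km from the metadata
#' coordinates; symmetric with a zero diagonal.
#'
#' @param metadata data frame with `sample_id`, `latitude`, `longitude`.
#' @return symmetric matrix of distances in km, dimnames = sample ids.
#' @export
pairwise_distance <- function(metadata) {
  if (anyNA(metadata$latitude) || anyNA(metadata$longitude)) {
    stop("missing coordinates in metadata")
  }
  xy <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(xy, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371000)
  }) / 1000
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  d
}

#' Greedily pair samples by ascending distance
#'
#' Matches samples of one habitat into pairs, taking candidate pairs in
#' ascending distance order subject to a distance cap; ties are broken by
#' lexicographic sample id so the pairing is deterministic. Unmatched
#' samples are reported as omitted, mirroring field designs where an odd or
#' isolated plot cannot be paired.
#'
#' @param metadata metadata for the samples to pair (typically one habitat).
#' @param distances distance matrix from [pairwise_distance()] (subset taken
#'   as needed).
#' @param max_km maximum within-pair distance.
#' @param same_block_preferred when TRUE, pairs within the same `block` are
#'   exhausted before any cross-block pair is considered.
#' @return list with `pairs` (data frame `unit_id`, `member1`, `member2`,
#'   `distance_km`) and `omitted` (character vector of unmatched ids).
#' @export
pair_samples <- function(metadata, distances, max_km,
                         same_block_preferred = FALSE) {
  ids <- sort(metadata$sample_id)
  if (length(ids) < 2) {
    return(list(pairs = data.frame(unit_id = character(0),
                                   member1 = character(0),
                                   member2 = character(0),
                                   distance_km = numeric(0),
                                   stringsAsFactors = FALSE),
                omitted = ids))
  }
  d <- distances[ids, ids, drop = FALSE]
  cand <- which(upper.tri(d) & d <= max_km, arr.ind = TRUE)
  if (nrow(cand)) {
    a <- ids[cand[, 1]]; b <- ids[cand[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    dd <- d[cand]
    same_block <- if (same_block_preferred) {
      blk <- metadata$block[match(ids, metadata$sample_id)]
      blk[cand[, 1]] == blk[cand[, 2]]
    } else rep(TRUE, length(dd))
    ord <- order(!same_block, dd, a, b)
    a <- a[ord]; b <- b[ord]; dd <- dd[ord]
  } else {
    a <- b <- character(0); dd <- numeric(0)
  }
  used <- character(0)
  pairs <- list()
  for (k in seq_along(a)) {
    if (a[k] %in% used || b[k] %in% used) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      member1 = a[k], member2 = b[k], distance_km = dd[k],
      stringsAsFactors = FALSE)
    used <- c(used, a[k], b[k])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(member1 = character(0), member2 = character(0),
               distance_km = numeric(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$member1), , drop = FALSE]
  pairs <- data.frame(unit_id = paste(pairs$member1, pairs$member2, sep = "+"),
                      pairs, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, omitted = setdiff(ids, used))
}

#' Pool paired samples into the next sampling grain
#'
#' Each pooled cell is the sum of its constituent cells, so abundance is
#' conserved exactly and `value_kind` is preserved.
#'
#' @param matrix abundance matrix at the current grain.
#' @param pairing data frame with `unit_id` and member columns (`member1`,
#'   `member2`, ... or a list-column `members`).
#' @return pooled [abundance_matrix()] with one row per unit.
#' @export
pool_samples <- function(matrix, pairing) {
  members <- if ("members" %in% names(pairing)) {
    pairing$members
  } else {
    mem_cols <- grep("^member", names(pairing), value = TRUE)
    lapply(seq_len(nrow(pairing)), function(i) {
      unlist(pairing[i, mem_cols], use.names = FALSE)
    })
  }
  all_members <- unlist(members)
  if (anyDuplicated(all_members)) {
    stop("sample(s) appear in more than one unit: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  missing <- setdiff(all_members, rownames(matrix))
  if (length(missing)) stop("pairing references unknown samples: ",
                            paste(missing, collapse = ", "))
  pooled <- t(vapply(members, function(ms) {
    colSums(unclass(matrix)[ms, , drop = FALSE])
  }, numeric(ncol(matrix))))
  rownames(pooled) <- pairing$unit_id
  colnames(pooled) <- colnames(matrix)
  abundance_matrix(pooled, value_kind(matrix))
}

#' Build the three-level nested grain hierarchy
#'
#' Grain 1 is the plot itself. Grain 2 pools proximity-pairs of plots within
#' each habitat (distance cap `caps[1]`, default 5 km); grain 3 pools pairs
#' of grain-2 units (cap `caps[2]`, default 45 km), so every grain-3 unit
#' contains exactly four plots and total sampled area is fixed within a
#' level. Plots or units that cannot be paired are omitted at that level and
#' logged, never silently dropped.
#'
#' @param matrix grain-1 abundance matrix (rows = plots).
#' @param metadata metadata covering all plots (habitat + coordinates).
#' @param caps named or positional numeric vector of distance caps in km for
#'   levels 2 and 3.
#' @param pairing_override optional list with elements `grain2` / `grain3`:
#'   explicit pairing data frames (as from [pair_samples()]) used instead of
#'   greedy matching at that level.
#' @param same_block_preferred passed to [pair_samples()].
#' @return list of class `grain_hierarchy` with one element per available
#'   level: `matrix`, `units` (unit -> constituent grain-1 plots),
#'   `metadata` (unit habitat + centroid coordinates), `omitted`.
#' @export
build_hierarchy <- function(matrix, metadata, caps = c(grain2 = 5, grain3 = 45),
                            pairing_override = NULL,
                            same_block_preferred = FALSE) {
  metadata <- validate_metadata(metadata, matrix)
  md1 <- metadata[match(rownames(matrix), metadata$sample_id), ]
  levels_out <- list()
  levels_out$grain1 <- list(
    matrix = matrix,
    units = stats::setNames(as.list(rownames(matrix)), rownames(matrix)),
    metadata = md1,
    omitted = character(0))

  pool_level <- function(prev, cap, override) {
    md <- prev$metadata
    pieces <- lapply(split(md, md$habitat), function(md_h) {
      if (!is.null(override)) {
        keep <- override$member1 %in% md_h$sample_id
        list(pairs = override[keep, , drop = FALSE],
             omitted = setdiff(md_h$sample_id,
                               unlist(override[keep, grep("^member", names(override))])))
      } else {
        d <- pairwise_distance(md_h)
        pair_samples(md_h, d, max_km = cap,
                     same_block_preferred = same_block_preferred)
      }
    })
    pairs <- do.call(rbind, lapply(pieces, `[[`, "pairs"))
    omitted <- unlist(lapply(pieces, `[[`, "omitted"), use.names = FALSE)
    if (is.null(pairs) || nrow(pairs) < 1) return(NULL)
    mat <- pool_samples(prev$matrix, pairs)
    units <- lapply(seq_len(nrow(pairs)), function(i) {
      sort(unlist(prev$units[c(pairs$member1[i], pairs$member2[i])],
                  use.names = FALSE))
    })
    names(units) <- pairs$unit_id
    idx1 <- match(pairs$member1, md$sample_id)
    idx2 <- match(pairs$member2, md$sample_id)
    md_new <- data.frame(
      sample_id = pairs$unit_id,
      habitat = md$habitat[idx1],
      block = ifelse(md$block[idx1] == md$block[idx2], md$block[idx1],
                     paste(md$block[idx1], md$block[idx2], sep = "|")),
      latitude = (md$latitude[idx1] + md$latitude[idx2]) / 2,
      longitude = (md$longitude[idx1] + md$longitude[idx2]) / 2,
      year = md$year[idx1],
      stringsAsFactors = FALSE)
    list(matrix = mat, units = units, metadata = md_new, omitted = omitted)
  }

  g2 <- pool_level(levels_out$grain1, caps[[1]], pairing_override$grain2)
  if (is.null(g2)) {
    warning("fewer than 2 poolable units at grain 2; hierarchy stops at grain 1")
  } else {
    levels_out$grain2 <- g2
    g3 <- pool_level(g2, caps[[2]], pairing_override$grain3)
    if (is.null(g3)) {
      warning("fewer than 2 poolable units at grain 3; hierarchy stops at grain 2")
    } else {
      levels_out$grain3 <- g3
    }
  }
  structure(levels_out, class = "grain_hierarchy")
}

#' @export
print.grain_hierarchy <- function(x, ...) {
  for (lv in names(x)) {
    md <- x[[lv]]$metadata
    tab <- table(md$habitat)
    cat(sprintf("%s: %d units (%s)%s\n", lv, nrow(x[[lv]]$matrix),
                paste(names(tab), tab, sep = " = ", collapse = ", "),
                if (length(x[[lv]]$omitted))
                  paste0("; omitted: ", paste(x[[lv]]$omitted, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Write a grain hierarchy membership table to CSV
#'
#' One row per (level, unit, member grain-1 plot).
#'
#' @param hierarchy a `grain_hierarchy` from [build_hierarchy()].
#' @param path output CSV.
#' @export
write_hierarchy <- function(hierarchy, path) {
  rows <- do.call(rbind, lapply(names(hierarchy), function(lv) {
    units <- hierarchy[[lv]]$units
    data.frame(level = lv,
               unit_id = rep(names(units), lengths(units)),
               member = unlist(units, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
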