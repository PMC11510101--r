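#' Validate and topologically sort a pedigree
#'
#' A pedigree is a data frame with character columns `id`, `sire`, `dam`;
#' unknown parents are `NA` (the readers also accept `0` and the empty
#' string).  Validation checks id uniqueness, creates founder records for
#' parents that appear only as parents (with a warning), detects cycles,
#' and reorders records so that every parent precedes its offspring.
#'
#' @param ped data frame with columns `id`, `sire`, `dam`.
#' @return the validated pedigree, parents before offspring, with an
#'   additional logical column `founder`.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$sire <- .clean_parent(ped$sire)
  ped$dam <- .clean_parent(ped$dam)
  if (anyDuplicated(ped$id))
    stop("duplicate animal ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    warning("adding ", length(parents),
            " parent(s) without own record as founders: ",
            paste(utils::head(parents, 5L), collapse = ", "))
    extra <- ped[0, ]
    add <- data.frame(id = parents, sire = NA_character_, dam = NA_character_,
                      stringsAsFactors = FALSE)
    for (nm in setdiff(names(ped), names(add))) add[[nm]] <- ped[[nm]][NA_integer_]
    ped <- rbind(add[, names(ped)], ped)
  }
  ord <- .topo_order(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  ped$founder <- is.na(ped$sire) & is.na(ped$dam)
  ped
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "" | x == "NA")] <- NA_character_
  x
}

# Kahn's algorithm; errors with an offending chain when a cycle exists.
.topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    # pop the smallest original index: stable, so an already-sorted
    # pedigree round-trips unchanged
    w <- which.min(queue)
    v <- queue[w]
    queue <- queue[-w]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[cyc], collapse = " -> "))
  }
  out
}
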