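# Trajectory CSV schema (one row per observed point; occluded frames are
# simply absent, though rows with NA/NaN coordinates are accepted on input
# and converted to occlusions):
#   track_id, group_id (optional), frame, time_s, x, y [, z]
#   [, sigma_x, sigma_y [, sigma_z]]
# Coordinates are continuous pixel units unless a pixelSize scale is applied
# at this boundary; times are seconds.

#' Read trajectories from CSV
#'
#' Validates and loads a trajectory table. Rows with missing coordinates
#' become occlusions (dropped with a notice); duplicated (track, frame) pairs
#' and non-increasing times are rejected with the offending row numbers;
#' absent sigma columns default the localization errors to zero with a
#' notice.
#'
#' @param path CSV file path.
#' @param pixelSize optional scale applied to coordinates and sigmas at read
#'   time (e.g. micrometers per pixel); default 1 (keep pixel units).
#' @return A named list of groups, each a named list of
#'   [Trajectory-class] objects.
#' @export
readTrajectories <- function(path, pixelSize = 1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "frame", "time_s", "x", "y")
  missingCols <- setdiff(req, names(df))
  if (length(missingCols))
    stop("missing required column(s): ", paste(missingCols, collapse = ", "),
         call. = FALSE)
  if (!"group_id" %in% names(df)) df$group_id <- "group1"
  dims <- c("x", "y", if ("z" %in% names(df)) "z")
  sigCols <- paste0("sigma_", dims)
  haveSig <- sigCols %in% names(df)
  if (!all(haveSig))
    message("no ", paste(sigCols[!haveSig], collapse = "/"),
            " column(s); localization errors default to 0")
  bad <- !stats::complete.cases(df[dims])
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with missing coordinates ",
            "(treated as occlusions)")
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df[c("track_id", "frame")])
  if (any(dup))
    stop("duplicated (track_id, frame) at row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  groups <- list()
  for (tid in unique(df$track_id)) {
    sub <- df[df$track_id == tid, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    nonMono <- which(diff(sub$time_s) <= 0)
    if (length(nonMono))
      stop("non-increasing time_s within track '", tid, "' near row(s): ",
           paste(rownames(sub)[nonMono + 1L], collapse = ", "),
           call. = FALSE)
    le <- matrix(0, nrow(sub), length(dims))
    for (j in seq_along(dims))
      if (haveSig[j]) le[, j] <- sub[[sigCols[j]]] * pixelSize
    gid <- as.character(sub$group_id[1L])
    tr <- Trajectory(times = sub$time_s,
                     coords = as.matrix(sub[dims]) * pixelSize,
                     locErrors = le, trackId = as.character(tid),
                     groupId = gid, frames = as.integer(sub$frame))
    groups[[gid]] <- c(groups[[gid]], setNames(list(tr), as.character(tid)))
  }
  groups
}

#' Write trajectories to CSV
#'
#' Inverse of [readTrajectories()] (canonical form: occluded frames absent).
#'
#' @param trajs a [Trajectory-class], a list of them, or the grouped list
#'   returned by [readTrajectories()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(trajs, path) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  if (length(trajs) && is.list(trajs[[1L]]))
    trajs <- unlist(trajs, recursive = FALSE)
  rows <- lapply(trajs, function(tr) {
    d <- nDims(tr)
    dims <- c("x", "y", "z")[seq_len(d)]
    out <- data.frame(track_id = trackId(tr), group_id = groupId(tr),
                      frame = tr@frames, time_s = tr@times)
    out[dims] <- tr@coords
    out[paste0("sigma_", dims)] <- tr@locErrors
    out
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

.paramsToList <- function(p) {
  list(D_alpha = p@D, alpha = p@alpha, mu = p@mu)
}

#' Write fit results to JSON (and a flat CSV table)
#'
#' Serializes per-track and per-group fits together with settings, seed and
#' software version. Numbers are written at full precision so a read-back
#' reproduces integers exactly and floats to better than 1e-12.
#'
#' @param trackFits named list of [FbmFit-class] (names = track ids); may be
#'   empty.
#' @param path output JSON path; a sibling `.csv` with the per-track table is
#'   written alongside.
#' @param ensembleFits optional named list of [FbmEnsembleFit-class]
#'   (names = group ids).
#' @param chains optional named list of [PosteriorChain-class] matching
#'   `trackFits` names; adds 95% credible intervals.
#' @param seed,settings provenance fields stored verbatim.
#' @return `path`, invisibly.
#' @export
writeResults <- function(trackFits, path, ensembleFits = list(),
                         chains = list(), seed = NA_integer_,
                         settings = list()) {
  tracks <- lapply(names(trackFits), function(nm) {
    f <- trackFits[[nm]]
    entry <- c(list(track_id = nm), .paramsToList(f@params),
               list(log_posterior = f@logPost, n_used = f@nUsed,
                    flagged = f@flagged))
    if (nm %in% names(chains)) {
      ci <- credibleIntervals(chains[[nm]])
      entry$credible_95 <- list(D_alpha = unname(ci["D", c(1L, 3L)]),
                                alpha = unname(ci["alpha", c(1L, 3L)]))
    }
    entry
  })
  groupsOut <- lapply(names(ensembleFits), function(nm) {
    f <- ensembleFits[[nm]]
    list(group_id = nm,
         substrate = .paramsToList(substrateParams(f)),
         particles = lapply(seq_along(particleParams(f)), function(k)
           c(list(track_id = trackId(f@ensemble@trajectories[[k]])),
             .paramsToList(particleParams(f)[[k]]))),
         log_posterior = f@logPost, flagged = f@flagged)
  })
  payload <- list(software = "fbmtrack",
                  version = as.character(utils::packageVersion("fbmtrack")),
                  seed = seed, settings = settings, tracks = tracks,
                  groups = groupsOut)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (length(tracks)) {
    tab <- do.call(rbind, lapply(tracks, function(e)
      data.frame(track_id = e$track_id, D_alpha = e$D_alpha,
                 alpha = e$alpha, log_posterior = e$log_posterior,
                 n_used = e$n_used, flagged = e$flagged)))
    write.csv(tab, sub("\\.json$", ".csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Export a posterior chain to CSV
#'
#' @param chain a [PosteriorChain-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeChain <- function(chain, path) {
  stopifnot(is(chain, "PosteriorChain"))
  df <- as.data.frame(chain@samples)
  df$log_posterior <- chain@logPost
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file path.
#' @return A list of numeric matrices, one per page (grayscale; multi-sample
#'   pages are averaged to one channel).
#' @export
readTiffStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1L, 2L), mean)
    p
  })
}
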