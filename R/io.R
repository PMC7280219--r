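# Disk formats: decay cubes as multi-page 16-bit TIFF (one page per time
# bin, lossless for integer counts) with a JSON sidecar for the axial/time
# metadata; lifetime maps as multi-channel 32-bit float TIFF; feature
# tables as CSV; models and cohort metadata as JSON.

#' Write one imaging site to a directory
#'
#' Each rendered section becomes \code{frame_<index>.tiff} (pages = time
#' bins); \code{site.json} records subject/site identity, the full depth
#' axis, which sections carry data, the time-bin width and the SG/SB layer
#' depths.
#'
#' @param site one imaging site (see \code{\link{generateSubject}})
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeSite <- function(site, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rendered <- which(!vapply(site$frames, is.null, logical(1)))
  tb <- NA_real_
  for (i in rendered) {
    cube <- site$frames[[i]]
    tb <- timeBinNs(cube)
    d <- dim(decayCounts(cube))
    if (max(cube@counts) > 65535)
      flim_error("flim_io", "counts exceed the 16-bit TIFF range")
    pages <- lapply(seq_len(d[3]),
                    function(k) cube@counts[, , k] / 65535)
    tiff::writeTIFF(pages, file.path(dir, sprintf("frame_%03d.tiff", i)),
                    bits.per.sample = 16L, compression = "deflate")
  }
  meta <- list(subject_id = site$subject_id, group = site$group_label,
               site = site$site, depth_um = site$depth_um,
               rendered = rendered, time_bin_ns = tb,
               sg_depth_um = site$sg_depth_um,
               sb_depth_um = site$sb_depth_um)
  jsonlite::write_json(meta, file.path(dir, "site.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an imaging site written by \code{\link{writeSite}}
#'
#' @param dir site directory
#' @return site list (frames, depth metadata, identity fields)
#' @export
readSite <- function(dir) {
  meta_path <- file.path(dir, "site.json")
  if (!file.exists(meta_path))
    flim_error("flim_io", "missing site.json in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- vector("list", length(meta$depth_um))
  for (i in meta$rendered) {
    f <- file.path(dir, sprintf("frame_%03d.tiff", i))
    if (!file.exists(f)) flim_error("flim_io", "missing %s", f)
    pages <- tiff::readTIFF(f, all = TRUE)
    counts <- round(simplify2array(pages) * 65535)
    frames[[i]] <- DecayCube(counts, meta$time_bin_ns, meta$depth_um[i])
  }
  list(subject_id = meta$subject_id, group_label = meta$group,
       site = meta$site, frames = frames, depth_um = meta$depth_um,
       sg_depth_um = meta$sg_depth_um, sb_depth_um = meta$sb_depth_um)
}

#' Write a cohort (sites + metadata) to a directory tree
#'
#' Sites land in \code{<subject_id>/<site>/}; \code{cohort.json} carries
#' subject ids, groups, clinical scores and the generative truth table.
#'
#' @param cohort a "SyntheticCohort"
#' @param dir output directory
#' @return the directory, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects)
    for (site in subj$sites)
      writeSite(site, file.path(dir, subj$subject_id, site$site))
  meta <- list(subjects = lapply(cohort$subjects, function(s)
    list(subject_id = s$subject_id, group = s$group_label,
         sites = vapply(s$sites, `[[`, character(1), "site"),
         pasi = s$pasi, lis = s$lis)),
    truth = cohort$truth)
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory
#' @param config analysis configuration to attach
#' @return a "SyntheticCohort"-shaped list
#' @export
readCohort <- function(dir, config = cohortConfig()) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE, simplifyDataFrame = TRUE)
  subj_meta <- meta$subjects
  subjects <- lapply(seq_len(nrow(subj_meta)), function(i) {
    row <- subj_meta[i, ]
    sites <- lapply(unlist(row$sites), function(snm)
      readSite(file.path(dir, row$subject_id, snm)))
    structure(list(subject_id = row$subject_id, group_label = row$group,
                   sites = sites,
                   pasi = if (is.null(row$pasi) || is.na(row$pasi))
                     NA_integer_ else as.integer(row$pasi),
                   lis = if (is.null(row$lis) || is.na(row$lis))
                     NA_integer_ else as.integer(row$lis),
                   truth = NULL),
              class = "SyntheticSubject")
  })
  structure(list(subjects = subjects, truth = meta$truth, config = config),
            class = "SyntheticCohort")
}

#' Write a lifetime map as multi-channel TIFF plus JSON sidecar
#'
#' Channels, in order: tau1, tau2, a1, a2, mean lifetime, mask. Each
#' parameter channel is min-max normalized for TIFF storage (32-bit
#' samples); the sidecar records the channel ranges for reconstruction,
#' the frame lifetime statistics, depth and stride. Masked pixels store 0
#' and are flagged by the mask channel.
#'
#' @param map a \linkS4class{LifetimeMap}
#' @param tiff_path output TIFF path
#' @param json_path sidecar path (default: tiff_path with .json)
#' @return tiff_path, invisibly
#' @export
writeLifetimeMap <- function(map, tiff_path,
                             json_path = sub("\\.tiff?$", ".json",
                                             tiff_path)) {
  chan_names <- c("tau1", "tau2", "a1", "a2", "mean_lifetime")
  chan <- lapply(chan_names, function(nm) slot(map, nm))
  ranges <- lapply(chan, function(m) range(m, na.rm = TRUE))
  norm <- mapply(function(m, r) {
    span <- if (r[2] > r[1]) r[2] - r[1] else 1
    m <- (m - r[1]) / span
    m[is.na(m)] <- 0
    m
  }, chan, ranges, SIMPLIFY = FALSE)
  norm[[6]] <- map@mask * 1
  tiff::writeTIFF(norm, tiff_path, bits.per.sample = 32L)
  st <- as.list(frameLifetimeStats(map))
  st$depth_um <- map@depth_um
  st$stride <- map@stride
  st$channels <- c(chan_names, "mask")
  st$channel_min <- vapply(ranges, `[`, numeric(1), 1)
  st$channel_max <- vapply(ranges, `[`, numeric(1), 2)
  jsonlite::write_json(st, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read a lifetime-map TIFF written by \code{\link{writeLifetimeMap}}
#'
#' @param tiff_path TIFF path
#' @param json_path sidecar path (default: tiff_path with .json)
#' @return a \linkS4class{LifetimeMap} (chi2 and photon counts are not
#'   stored and come back as NA)
#' @export
readLifetimeMap <- function(tiff_path,
                            json_path = sub("\\.tiff?$", ".json",
                                            tiff_path)) {
  st <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  chans <- tiff::readTIFF(tiff_path, all = TRUE)
  mask <- chans[[6]] > 0.5
  restore <- function(i) {
    span <- st$channel_max[i] - st$channel_min[i]
    m <- chans[[i]] * (if (span > 0) span else 1) + st$channel_min[i]
    m[!mask] <- NA_real_
    m
  }
  tau1 <- restore(1); tau2 <- restore(2)
  a1 <- restore(3); a2 <- restore(4)
  s <- a1 + a2
  na <- matrix(NA_real_, nrow(mask), ncol(mask))
  new("LifetimeMap", tau1 = tau1, tau2 = tau2, a1 = a1, a2 = a2,
      mean_lifetime = restore(5), p1 = 100 * a1 / s, p2 = 100 * a2 / s,
      chi2 = na, n_photons = na, mask = mask,
      depth_um = st$depth_um, stride = as.integer(st$stride))
}

#' Write / read a feature table as CSV
#'
#' The schema header (column order) is part of the contract and is stable
#' across runs.
#'
#' @param table feature data.frame
#' @param path CSV path
#' @return path, invisibly
#' @export
writeFeatureTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a severity model as JSON
#'
#' Serializes the standardization parameters, loadings, explained-variance
#' ratios, orientation sign and feature schema.
#'
#' @param model a \linkS4class{SeverityModel}
#' @param path JSON path
#' @return path, invisibly
#' @export
writeSeverityModel <- function(model, path) {
  jsonlite::write_json(list(
    features = model@features, center = model@center, scale = model@scale,
    rotation = model@rotation,
    explained_variance_ratio = model@explained_variance_ratio,
    pc1_sign = model@pc1_sign), path, digits = NA)
  invisible(path)
}

#' @rdname writeSeverityModel
#' @export
readSeverityModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- as.matrix(j$rotation)
  rownames(rot) <- j$features
  new("SeverityModel", center = stats::setNames(j$center, j$features),
      scale = stats::setNames(j$scale, j$features), rotation = rot,
      explained_variance_ratio = j$explained_variance_ratio,
      pc1_sign = j$pc1_sign, features = j$features)
}
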