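# Map-bundle exchange format. The clinical mapping system's export is
# proprietary, so studies travel as a bespoke plain-text bundle:
#   study.json            subjects + map metadata
#   points_<map_id>.csv   point_id,x_mm,y_mm,z_mm,lat_ms,rt_ms
#   uni_<map_id>.csv      one line per point: point_id,fs,qrs_on,qrs_end,t_end,<samples...>
#   bip_<map_id>.csv      same layout as uni_*
#   sites.csv             site_id,vt_id,phase,x_mm,y_mm,z_mm
# ari_ms is derived (rt - lat) on read, never stored.

fmt_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[!is.finite(x)] <- "NA"
  out
}

#' Write a study as a map bundle
#'
#' Serializes a validated study to a directory of plain-text files with a
#' deterministic byte layout (the same study always produces identical files).
#'
#' @param study a `vts_study` (validated before writing).
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_map_bundle()]
#' @export
write_map_bundle <- function(study, path) {
  validate_study(study)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create bundle directory: ", path))
  }
  meta <- list(
    subjects = study$subjects,
    maps = lapply(seq_len(nrow(study$maps)), function(i) {
      as.list(study$maps[i, c("map_id", "subject_id", "rhythm", "protocol")])
    })
  )
  jsonlite::write_json(meta, file.path(path, "study.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  s <- study$sites
  site_lines <- c("site_id,vt_id,phase,x_mm,y_mm,z_mm",
                  if (nrow(s)) paste(s$site_id, s$vt_id, s$phase,
                                     fmt_num(s$x_mm), fmt_num(s$y_mm),
                                     fmt_num(s$z_mm), sep = ","))
  writeLines(site_lines, file.path(path, "sites.csv"))

  for (mid in study$maps$map_id) {
    p <- study$points[study$points$map_id == mid, ]
    pt_lines <- c("point_id,x_mm,y_mm,z_mm,lat_ms,rt_ms",
                  if (nrow(p)) paste(p$point_id,
                                     fmt_num(p$x_mm), fmt_num(p$y_mm), fmt_num(p$z_mm),
                                     fmt_num(p$lat_ms), fmt_num(p$rt_ms), sep = ","))
    writeLines(pt_lines, file.path(path, sprintf("points_%s.csv", mid)))
    for (chan in c("uni", "bip")) {
      lines <- c("point_id,fs,qrs_on,qrs_end,t_end,samples",
                 vapply(seq_len(nrow(p)), function(i) {
                   tr <- p[[chan]][[i]]
                   paste(c(p$point_id[i], fmt_num(tr$fs), tr$qrs_on, tr$qrs_end,
                           tr$t_end, fmt_num(tr$samples)), collapse = ",")
                 }, character(1)))
      writeLines(lines, file.path(path, sprintf("%s_%s.csv", chan, mid)))
    }
  }
  invisible(path)
}

read_signal_file <- function(file, kind) {
  if (!file.exists(file)) abort(paste0("bundle is missing file: ", file))
  lines <- readLines(file)[-1L]
  lapply(lines, function(ln) {
    v <- strsplit(ln, ",", fixed = TRUE)[[1]]
    list(point_id = v[1],
         trace = egm_trace(as.numeric(v[-(1:5)]), fs = as.numeric(v[2]),
                           kind = kind, qrs_on = as.integer(v[3]),
                           qrs_end = as.integer(v[4]), t_end = as.integer(v[5])))
  })
}

#' Read a map bundle into a study
#'
#' Inverse of [write_map_bundle()]: reads the bundle directory, reassembles
#' traces and annotations, derives `ari_ms = rt_ms - lat_ms` and validates
#' every invariant before returning.
#'
#' @param path bundle directory.
#' @return A validated `vts_study`.
#' @export
read_map_bundle <- function(path) {
  meta_file <- file.path(path, "study.json")
  if (!file.exists(meta_file)) abort(paste0("bundle is missing file: ", meta_file))
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  maps <- dplyr::bind_rows(lapply(meta$maps, as_tibble))

  sites_file <- file.path(path, "sites.csv")
  if (!file.exists(sites_file)) abort(paste0("bundle is missing file: ", sites_file))
  sites <- as_tibble(read.csv(sites_file, colClasses = c(
    site_id = "character", vt_id = "character", phase = "character")))

  points <- purrr::map_dfr(maps$map_id, function(mid) {
    pfile <- file.path(path, sprintf("points_%s.csv", mid))
    if (!file.exists(pfile)) abort(paste0("bundle is missing file: ", pfile))
    p <- as_tibble(read.csv(pfile, colClasses = c(point_id = "character")))
    uni <- read_signal_file(file.path(path, sprintf("uni_%s.csv", mid)), "unipolar")
    bip <- read_signal_file(file.path(path, sprintf("bip_%s.csv", mid)), "bipolar")
    if (length(uni) != nrow(p) || length(bip) != nrow(p)) {
      abort(sprintf("map %s: points table and signal rows disagree (%d points, %d uni, %d bip)",
                    mid, nrow(p), length(uni), length(bip)))
    }
    sig_ids <- vapply(uni, `[[`, character(1), "point_id")
    if (!identical(sig_ids, p$point_id)) {
      abort(sprintf("map %s: signal rows do not match points table order", mid))
    }
    p$map_id <- mid
    p$ari_ms <- p$rt_ms - p$lat_ms
    p$uni <- lapply(uni, `[[`, "trace")
    p$bip <- lapply(bip, `[[`, "trace")
    p[, c("map_id", "point_id", "x_mm", "y_mm", "z_mm",
          "lat_ms", "rt_ms", "ari_ms", "uni", "bip")]
  })

  new_study(subjects = unlist(meta$subjects), maps = maps,
            points = points, sites = sites)
}
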