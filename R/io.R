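#' @name io_formats
#' @title File formats: echo volumes, film scans, dose maps, reports
#' @description
#' Readers and writers for the pipeline's exchange formats. Echo volumes
#' travel as NIfTI files with JSON sidecars carrying the echo time (the
#' BIDS convention); film scans as 16-bit grayscale TIFF with a JSON
#' sidecar holding the scan dpi; dose maps as long-format CSV
#' (x, y, z, dose) plus a JSON grid-metadata sidecar. All writers produce
#' files their readers round-trip exactly.
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' Write a dual-echo pair as two NIfTI volumes with JSON sidecars
#'
#' @param pair an [echo_image_pair()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; default `"echo"`.
#' @return Character vector of the two NIfTI paths (sidecars sit next to
#'   them).
#' @export
write_echo_series <- function(pair, dir, prefix = "echo") {
  stopifnot(inherits(pair, "echo_image_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s%d.nii", prefix, 1:2))
  tes <- c(pair$te1, pair$te2)
  imgs <- list(pair$s1, pair$s2)
  for (i in 1:2) {
    arr <- imgs[[i]]
    attr(arr, "pixdim") <- pair$grid$spacing[seq_along(dim(arr))]
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), paths[i])
    jsonlite::write_json(
      list(EchoTime = tes[i] / 1000,  # seconds, BIDS convention
           EchoTimeMs = tes[i],
           GridShape = pair$grid$shape,
           GridSpacingMm = pair$grid$spacing,
           GridOriginMm = pair$grid$origin),
      sidecar_path(paths[i]), auto_unbox = TRUE, digits = NA)
  }
  paths
}

#' Read a dual-echo pair from two NIfTI volumes
#'
#' Echo times are taken from the JSON sidecars; the two volumes must agree
#' in geometry. The pair is returned with TE1 < TE2.
#'
#' @param paths character vector of the two NIfTI paths.
#' @return An [echo_image_pair()].
#' @export
read_echo_series <- function(paths) {
  if (length(paths) != 2L) stop("'paths' must name exactly two volumes")
  if (!all(file.exists(paths))) stop("missing echo volume: ",
                                     paths[!file.exists(paths)][1])
  sc <- lapply(paths, function(p) {
    sp <- sidecar_path(p)
    if (!file.exists(sp)) stop("missing echo-time sidecar: ", sp)
    jsonlite::read_json(sp, simplifyVector = TRUE)
  })
  for (s in sc) if (is.null(s$EchoTimeMs)) stop("sidecar lacks EchoTimeMs")
  imgs <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    array(as.numeric(img), dim = dim(img))
  })
  if (!identical(dim(imgs[[1]]), dim(imgs[[2]])))
    stop("geometry mismatch between echo volumes")
  g1 <- sc[[1]]; g2 <- sc[[2]]
  if (!isTRUE(all.equal(g1$GridShape, g2$GridShape)) ||
      !isTRUE(all.equal(g1$GridSpacingMm, g2$GridSpacingMm)) ||
      !isTRUE(all.equal(g1$GridOriginMm, g2$GridOriginMm)))
    stop("geometry mismatch between echo sidecars")
  grid <- grid_spec(g1$GridShape, g1$GridSpacingMm, g1$GridOriginMm)
  ord <- order(c(sc[[1]]$EchoTimeMs, sc[[2]]$EchoTimeMs))
  echo_image_pair(imgs[[ord[1]]], imgs[[ord[2]]],
                  sc[[ord[1]]]$EchoTimeMs, sc[[ord[2]]]$EchoTimeMs, grid)
}

#' Write a film scan as 16-bit grayscale TIFF with a dpi sidecar
#'
#' @param scan a [film_scan()].
#' @param path output `.tif` path.
#' @return The path, invisibly.
#' @export
write_film_scan <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  px <- round(pmin(pmax(scan$pixels, 0), 65535))
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(dpi = 25.4 / scan$pixel_spacing, channel = scan$channel),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a film scan image
#'
#' Accepts 8/16-bit grayscale or color TIFF/PNG. For color images one
#' channel is extracted (red by default — standard radiochromic practice).
#' Pixel spacing comes from the embedded TIFF resolution if present, else
#' from the JSON sidecar written by [write_film_scan()], else from
#' `dpi_override`; with none of these the read fails.
#'
#' @param path image path (`.tif`/`.tiff`/`.png`).
#' @param channel `"red"`, `"green"`, `"blue"` or `"gray"`.
#' @param dpi_override optional dpi when the file carries none.
#' @return A [film_scan()] with pixels on the 16-bit scale.
#' @export
read_film_scan <- function(path, channel = "red", dpi_override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  dpi <- NULL
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    if (!is.null(bps) && !bps %in% c(8L, 16L))
      stop("unsupported bit depth: ", bps)
    res <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    if (!is.null(res) && is.finite(res) && res > 0)
      dpi <- if (!is.null(unit) && identical(unit, "cm")) res * 2.54 else res
  } else if (ext == "png") {
    img <- png::readPNG(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3L) {
    ch <- match(channel, c("red", "green", "blue"))
    if (is.na(ch)) stop("color image: 'channel' must be red, green or blue")
    if (dim(img)[3] < ch) stop("image lacks the requested channel")
    img <- img[, , ch]
  } else channel <- "gray"
  img <- matrix(as.numeric(img), nrow(img), ncol(img))  # drop TIFF attributes
  if (is.null(dpi) && file.exists(sidecar_path(path))) {
    sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (!is.null(sc$dpi)) dpi <- sc$dpi
  }
  if (is.null(dpi)) {
    if (is.null(dpi_override))
      stop("image carries no dpi and no 'dpi_override' was given")
    dpi <- dpi_override
  }
  film_scan(round(img * 65535), pixel_spacing = 25.4 / dpi,
            channel = channel)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a dose grid as CSV plus JSON grid metadata
#'
#' One row per voxel (`x`, `y`, `z` in mm, `dose` in Gy, `valid`,
#' `saturated`), with fixed numeric formatting so identical inputs produce
#' byte-identical files.
#'
#' @param dose a [dose_grid()].
#' @param path output `.csv` path; metadata goes to `path.json`.
#' @return The CSV path, invisibly.
#' @export
write_dose_csv <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!any(dose$valid)) stop("refusing to write an all-invalid dose grid")
  ax <- lapply(1:3, grid_axis, grid = dose$grid)
  sh <- dose$grid$shape
  df <- data.frame(
    x = rep(ax[[1]], times = sh[2] * sh[3]),
    y = rep(rep(ax[[2]], each = sh[1]), times = sh[3]),
    z = rep(ax[[3]], each = sh[1] * sh[2]),
    dose = as.vector(dose$dose),
    valid = as.integer(as.vector(dose$valid)),
    saturated = as.integer(as.vector(dose$saturated)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("x,y,z,dose,valid,saturated", con)
  lines <- paste(fmt_num(df$x), fmt_num(df$y), fmt_num(df$z),
                 ifelse(is.na(df$dose), "NA", fmt_num(df$dose)),
                 df$valid, df$saturated, sep = ",")
  writeLines(lines, con)
  jsonlite::write_json(
    list(shape = dose$grid$shape, spacing_mm = dose$grid$spacing,
         origin_mm = dose$grid$origin, provenance = dose$provenance,
         dose_unit = "Gy"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dose grid written by [write_dose_csv()]
#'
#' @param path the `.csv` path (its `.json` sidecar must sit next to it).
#' @return A [dose_grid()].
#' @export
read_dose_csv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  grid <- grid_spec(meta$shape, meta$spacing_mm, meta$origin_mm)
  dose_grid(array(df$dose, dim = grid$shape), grid,
            valid = array(df$valid == 1L, dim = grid$shape),
            saturated = array(df$saturated == 1L, dim = grid$shape),
            provenance = meta$provenance)
}

#' Write the QA run outputs with a hashed manifest
#'
#' Writes the truth/reconstructed dose maps (CSV + JSON), the QA report
#' (JSON), and rendered isodose PNGs into `dir`, then a `manifest.json`
#' listing every file with its MD5 content hash. Numeric formatting is
#' fixed, so repeated runs from identical inputs produce byte-identical
#' payloads and identical hashes.
#'
#' @param dose a [dose_grid()] (typically the reconstructed map).
#' @param report a `qa_report` from [run_qa_pipeline()], or any list
#'   serializable to JSON.
#' @param dir output directory.
#' @param extra_doses optional named list of further [dose_grid()]s to
#'   write alongside.
#' @return The manifest as a data frame (`file`, `md5`), invisibly.
#' @export
write_outputs <- function(dose, report, dir, extra_doses = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  p <- file.path(dir, "dose_map.csv")
  write_dose_csv(dose, p)
  written <- c(written, p, sidecar_path(p))
  png_path <- file.path(dir, "dose_map_isodose.png")
  write_isodose_png(dose, png_path)
  written <- c(written, png_path, sidecar_path(png_path))
  if (!is.null(extra_doses))
    for (nm in names(extra_doses)) {
      p <- file.path(dir, paste0("dose_map_", nm, ".csv"))
      write_dose_csv(extra_doses[[nm]], p)
      written <- c(written, p, sidecar_path(p))
    }
  rp <- file.path(dir, "qa_report.json")
  jsonlite::write_json(unclass(report), rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  written <- c(written, rp)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
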