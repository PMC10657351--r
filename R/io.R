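#' Read a 3D point cloud from OBJ, PLY (ascii) or XYZ text
#'
#' Extracts vertex coordinates only; faces, normals and colors are ignored.
#'
#' @param path File path; format detected from the extension (`.obj`,
#'   `.ply`, anything else is treated as whitespace-separated XYZ).
#' @return An n x 3 numeric matrix.
#' @export
read_pointcloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  pts <- switch(ext,
    obj = {
      v <- lines[startsWith(lines, "v ")]
      if (!length(v)) stop("no vertex lines in OBJ file: ", path)
      do.call(rbind, lapply(strsplit(trimws(sub("^v ", "", v)), "\\s+"),
                            function(f) as.numeric(f[1:3])))
    },
    ply = {
      hdr_end <- match("end_header", trimws(lines))
      if (is.na(hdr_end)) stop("not an ascii PLY file: ", path)
      nv_line <- grep("^element vertex", lines, value = TRUE)
      nv <- as.integer(sub("element vertex\\s+", "", nv_line[1]))
      body <- lines[(hdr_end + 1):(hdr_end + nv)]
      do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                            function(f) as.numeric(f[1:3])))
    },
    {
      keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
      do.call(rbind, lapply(strsplit(trimws(lines[keep]), "[,[:space:]]+"),
                            function(f) as.numeric(f[1:3])))
    }
  )
  if (anyNA(pts)) stop("malformed coordinates in ", path)
  unname(pts)
}

#' Read a specimen manifest
#'
#' A TSV with columns `specimen`, `species`, `mass_g`, `wrist_x`, `file`.
#' Missing masses (`NA`) are filled from an optional two-column species-mean
#' table (`species`, `mass_g`).
#'
#' @param path Manifest TSV path.
#' @param mass_table Optional path to the species-mean mass fallback table.
#' @return A data.frame.
#' @export
read_manifest <- function(path, mass_table = NULL) {
  mf <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("specimen", "species", "mass_g", "wrist_x", "file")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyNA(mf$mass_g)) {
    if (is.null(mass_table))
      stop("manifest has missing masses and no mass_table was supplied")
    mt <- utils::read.table(mass_table, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    idx <- match(mf$species[is.na(mf$mass_g)], mt$species)
    mf$mass_g[is.na(mf$mass_g)] <- mt$mass_g[idx]
    if (anyNA(mf$mass_g)) stop("mass missing for some species even after fallback")
  }
  mf
}

#' Measure every scan listed in a manifest
#'
#' Reads each point cloud, aligns, slices, measures, mass-scales and
#' summarizes to species-median trait profiles.
#'
#' @param manifest A data.frame from [read_manifest()] (paths in `file`
#'   resolved relative to `dir`).
#' @param dir Base directory for scan files.
#' @param n_hw Handwing slice count.
#' @param align Align clouds before slicing?
#' @param scale Mass-scale the traits?
#' @return A named list of `"trait_profile"` objects (see
#'   [summarize_species()]).
#' @export
measure_manifest <- function(manifest, dir = ".", n_hw = 25L, align = TRUE,
                             scale = TRUE) {
  tables <- lapply(seq_len(nrow(manifest)), function(i) {
    pts <- read_pointcloud(file.path(dir, manifest$file[i]))
    sc <- wing_scan(pts, species_id = manifest$species[i],
                    body_mass = manifest$mass_g[i],
                    wrist_x = manifest$wrist_x[i],
                    specimen_id = manifest$specimen[i])
    measure_wing(sc, n_hw = n_hw, align = align, scale = scale)
  })
  summarize_species(tables)
}

#' Write a span profile as TSV
#'
#' @param profile A `"span_profile"` data.frame.
#' @param path Output path.
#' @param trait Trait name column to include.
#' @export
write_span_profile <- function(profile, path, trait = NA_character_) {
  df <- as.data.frame(profile)
  df$trait <- trait
  df$statistic <- attr(profile, "statistic") %||% NA_character_
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
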