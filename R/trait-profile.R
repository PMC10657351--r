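#' Construct a species-by-slice trait profile
#'
#' The standard container for one shape trait measured over standardized
#' spanwise wing slices: a numeric matrix with species as rows and slices as
#' columns (ordered base to tip), plus a region label per slice.
#'
#' @param values Species x slice numeric matrix with species rownames.
#' @param trait Trait name, one of `"camber"`, `"chord"`, `"xst"`, `"xsa"`
#'   (other names allowed for synthetic traits).
#' @param regions Character vector, one of `"AW"`, `"WRIST"`, `"HW"` per
#'   column. Defaults to the standard 10 AW + 25 HW layout when the matrix
#'   has 35 columns, or 10 AW + 1 WRIST + 25 HW when it has 36.
#' @param scaled Logical: mass-scaled values?
#' @param transform `"raw"` or `"log10"`.
#' @return An object of class `"trait_profile"`.
#' @export
trait_profile <- function(values, trait = "trait", regions = NULL,
                          scaled = TRUE, transform = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have species rownames")
  if (is.null(regions)) regions <- default_regions(ncol(values))
  if (length(regions) != ncol(values))
    stop("regions must have one label per slice column")
  if (!all(regions %in% c("AW", "WRIST", "HW")))
    stop("regions must be AW, WRIST or HW")
  structure(list(trait = trait, values = values, regions = regions,
                 scaled = scaled, transform = transform),
            class = "trait_profile")
}

default_regions <- function(p) {
  if (p == 35) c(rep("AW", 10), rep("HW", 25))
  else if (p == 36) c(rep("AW", 10), "WRIST", rep("HW", 25))
  else stop("cannot infer regions for ", p, " slices; supply `regions`")
}

#' @export
print.trait_profile <- function(x, ...) {
  cat(sprintf("trait_profile: %s (%s, %s), %d species x %d slices (%d AW, %d wrist, %d HW)\n",
              x$trait, if (x$scaled) "mass-scaled" else "raw units", x$transform,
              nrow(x$values), ncol(x$values), sum(x$regions == "AW"),
              sum(x$regions == "WRIST"), sum(x$regions == "HW")))
  invisible(x)
}

as_profile_matrix <- function(profile) {
  if (inherits(profile, "trait_profile")) profile$values
  else as.matrix(profile)
}

profile_regions <- function(profile, p) {
  if (inherits(profile, "trait_profile")) profile$regions
  else default_regions(p)
}

#' Drop or reassign the wrist slice of a trait profile
#'
#' @param profile A `"trait_profile"`.
#' @param policy `"excluded"` (drop the wrist column; the default 35-slice
#'   analysis layout), `"to_HW"` or `"to_AW"` (relabel it).
#' @return The adjusted `"trait_profile"`.
#' @export
apply_wrist_policy <- function(profile, policy = c("excluded", "to_HW", "to_AW")) {
  policy <- match.arg(policy)
  w <- which(profile$regions == "WRIST")
  if (!length(w)) return(profile)
  if (policy == "excluded") {
    profile$values <- profile$values[, -w, drop = FALSE]
    profile$regions <- profile$regions[-w]
  } else {
    profile$regions[w] <- if (policy == "to_HW") "HW" else "AW"
  }
  profile
}

#' Log10-transform a trait profile
#'
#' Used ahead of the covariance-ratio test to remove the biasing effect of
#' different trait means between wing regions.
#'
#' @param profile A `"trait_profile"` with positive values.
#' @export
log10_profile <- function(profile) {
  if (any(profile$values <= 0, na.rm = TRUE))
    stop("log10 transform requires strictly positive values")
  profile$values <- log10(profile$values)
  profile$transform <- "log10"
  profile
}

#' Write / read trait profiles as wide TSV
#'
#' Columns are named `<trait>_s01 .. <trait>_sNN`; rows are species.
#'
#' @param profile A `"trait_profile"`.
#' @param path Output file path.
#' @export
write_trait_profile <- function(profile, path) {
  m <- profile$values
  colnames(m) <- sprintf("%s_s%02d", profile$trait, seq_len(ncol(m)))
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- paste(profile$regions, collapse = ",")
  writeLines(c(paste0("# regions: ", reg),
               paste0("# scaled: ", profile$scaled),
               paste0("# transform: ", profile$transform)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trait_profile
#' @param trait Trait name to record on the read profile.
#' @export
read_trait_profile <- function(path, trait = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  if (is.null(trait)) trait <- sub("_s[0-9]+$", "", colnames(m)[1])
  meta <- paste0(path, ".meta")
  regions <- NULL; scaled <- TRUE; transform <- "raw"
  if (file.exists(meta)) {
    ln <- readLines(meta)
    rg <- sub("^# regions: ", "", ln[startsWith(ln, "# regions:")])
    if (length(rg)) regions <- strsplit(rg, ",")[[1]]
    sc <- sub("^# scaled: ", "", ln[startsWith(ln, "# scaled:")])
    if (length(sc)) scaled <- as.logical(sc)
    tf <- sub("^# transform: ", "", ln[startsWith(ln, "# transform:")])
    if (length(tf)) transform <- tf
  }
  trait_profile(m, trait = trait, regions = regions, scaled = scaled,
                transform = transform)
}
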