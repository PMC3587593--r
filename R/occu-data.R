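#' Canonical habitat vocabulary
#'
#' The five urban habitat strata used throughout the package, in display
#' order: closed-canopy forest fragments, mown amenity space, and three
#' residential classes of decreasing garden size and green cover.
#'
#' @return Character vector of the five canonical habitat labels.
#' @export
habitat_levels <- function() {
  c("Forest", "Amenity", "Res1", "Res2", "Res3")
}

#' The three residential habitat labels
#' @return Character vector `c("Res1", "Res2", "Res3")`.
#' @export
residential_levels <- function() {
  c("Res1", "Res2", "Res3")
}

# Map free-form habitat spellings onto the closed vocabulary.
# Case-insensitive; spaces/underscores around the residential index ignored
# ("res 1", "RES_2" -> "Res1", "Res2"). Unknown labels come back as NA.
canonical_habitat <- function(x) {
  key <- tolower(gsub("[ _-]", "", as.character(x)))
  lookup <- c(
    forest = "Forest", forestfragment = "Forest",
    amenity = "Amenity",
    res1 = "Res1", residential1 = "Res1",
    res2 = "Res2", residential2 = "Res2",
    res3 = "Res3", residential3 = "Res3"
  )
  out <- lookup[key]
  names(out) <- NULL
  out
}

#' Construct a validated occupancy dataset
#'
#' Bundles one row per surveyed site: a habitat class, `J` replicate
#' detection outcomes (the detection history), and optional site covariates
#' (a binary supplementary-food indicator and the proportion of forest
#' fragment within a buffer around the site). The replicates are treated as
#' exchangeable repeat surveys within a single visit; no ordering between
#' them is assumed.
#'
#' @param sites Data frame with columns `site_id`, `habitat`, `y1`..`yJ`
#'   and optionally `food` (0/1) and `forest_area` (proportion in `[0,1]`).
#'   Detection cells may be `NA` for lost or unreadable replicates.
#' @param habitat_areas Optional named numeric vector of habitat extents in
#'   hectares, used by [occupied_area_table()].
#' @return An object of class `occu_data`: a list with elements `sites`
#'   (the validated data frame, habitat canonicalized), `J` (replicate
#'   count) and `habitat_areas`.
#' @examples
#' d <- occu_data(data.frame(
#'   site_id = c("a", "b"), habitat = c("Forest", "Res1"),
#'   y1 = c(1, 0), y2 = c(0, 0), y3 = c(1, 0)
#' ))
#' d$J
#' @export
occu_data <- function(sites, habitat_areas = NULL) {
  stopifnot(is.data.frame(sites))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) {
    stop("dataset must contain at least one site", call. = FALSE)
  }
  required <- c("site_id", "habitat")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ycols <- grep("^y[0-9]+$", names(sites), value = TRUE)
  if (length(ycols) == 0L) {
    stop("no replicate detection columns y1..yJ found", call. = FALSE)
  }
  ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
  J <- length(ycols)

  sites$site_id <- as.character(sites$site_id)
  dup <- duplicated(sites$site_id)
  if (any(dup)) {
    stop("duplicate site_id: ", paste(unique(sites$site_id[dup]), collapse = ", "),
      call. = FALSE
    )
  }

  canon <- canonical_habitat(sites$habitat)
  bad <- which(is.na(canon))
  if (length(bad)) {
    stop(sprintf(
      "unknown habitat label %s in row %d (allowed: %s)",
      dQuote(as.character(sites$habitat[bad[1]])), bad[1],
      paste(habitat_levels(), collapse = ", ")
    ), call. = FALSE)
  }
  sites$habitat <- factor(canon, levels = habitat_levels())

  for (cn in ycols) {
    v <- sites[[cn]]
    if (is.character(v)) v[v %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.numeric(v))
    ok <- is.na(v) | v %in% c(0, 1)
    if (!all(ok)) {
      stop(sprintf(
        "non-binary detection value %s in column %s, row %d",
        dQuote(as.character(sites[[cn]][which(!ok)[1]])), cn, which(!ok)[1]
      ), call. = FALSE)
    }
    sites[[cn]] <- v
  }

  if (!is.null(sites$food)) {
    f <- suppressWarnings(as.numeric(sites$food))
    if (any(!is.na(f) & !f %in% c(0, 1))) {
      stop("food must be binary 0/1", call. = FALSE)
    }
    sites$food <- f
  }
  if (!is.null(sites$forest_area)) {
    a <- suppressWarnings(as.numeric(sites$forest_area))
    if (any(!is.na(a) & (a < 0 | a > 1))) {
      stop("forest_area must be a proportion in [0, 1]", call. = FALSE)
    }
    sites$forest_area <- a
  }

  if (!is.null(habitat_areas)) {
    habitat_areas <- unlist(habitat_areas)
    hn <- canonical_habitat(names(habitat_areas))
    if (any(is.na(hn))) {
      stop("unknown habitat label in habitat_areas", call. = FALSE)
    }
    names(habitat_areas) <- hn
    if (any(habitat_areas < 0)) stop("habitat areas must be >= 0", call. = FALSE)
  }

  structure(
    list(
      sites = sites[, c("site_id", "habitat", ycols,
        intersect(c("food", "forest_area"), names(sites))), drop = FALSE],
      J = J,
      habitat_areas = habitat_areas
    ),
    class = "occu_data"
  )
}

#' @export
print.occu_data <- function(x, ...) {
  cat(sprintf(
    "occupancy dataset: %d sites, %d replicate surveys per site\n",
    nrow(x$sites), x$J
  ))
  tab <- table(droplevels(x$sites$habitat))
  cat("sites per habitat:",
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cov <- intersect(c("food", "forest_area"), names(x$sites))
  if (length(cov)) cat("covariates:", paste(cov, collapse = ", "), "\n")
  invisible(x)
}

# replicate columns of a dataset, in order
y_columns <- function(data) paste0("y", seq_len(data$J))

# n x J numeric matrix of detection outcomes (NA = missing replicate)
detection_matrix <- function(data) {
  as.matrix(data$sites[, y_columns(data), drop = FALSE])
}

#' Read a detection/covariate table from delimited text
#'
#' Expects a header row naming `site_id`, `habitat`, `y1`..`yJ`, and
#' optionally `food` and `forest_area`. Empty cells and the literal string
#' `NA` in replicate columns are parsed as missing observations, never as
#' non-detections.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param habitat_areas Optional habitat-area vector or path to a 2-column
#'   `habitat,area_ha` file (see [read_habitat_areas()]).
#' @return An [occu_data] object.
#' @export
read_dataset <- function(path, sep = ",", habitat_areas = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    na.strings = c("NA", ""), fileEncoding = "UTF-8"
  )
  if (is.character(habitat_areas) && length(habitat_areas) == 1L) {
    habitat_areas <- read_habitat_areas(habitat_areas, sep = sep)
  }
  occu_data(df, habitat_areas = habitat_areas)
}

#' Write a dataset back to delimited text
#'
#' Inverse of [read_dataset()]; missing replicate cells are written as `NA`.
#'
#' @param data An [occu_data] object.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "occu_data"))
  out <- data$sites
  out$habitat <- as.character(out$habitat)
  utils::write.table(out, path,
    sep = sep, row.names = FALSE, quote = FALSE, na = "NA",
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a habitat-area table
#'
#' @param path Delimited file with header `habitat,area_ha`.
#' @param sep Field separator.
#' @return Named numeric vector of hectares.
#' @export
read_habitat_areas <- function(path, sep = ",") {
  df <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE, fileEncoding = "UTF-8"
  )
  stopifnot(all(c("habitat", "area_ha") %in% names(df)))
  stats::setNames(as.numeric(df$area_ha), df$habitat)
}

#' Per-habitat survey and detection counts
#'
#' For each habitat, the number of surveyed sites and the number with at
#' least one detection across the replicate surveys. Sites whose replicates
#' are all missing count as surveyed but undetected and are flagged in the
#' `all_missing` column.
#'
#' @param data An [occu_data] object.
#' @return Data frame with columns `habitat`, `sites`, `detected`,
#'   `all_missing` and `naive` (= detected / sites), one row per habitat
#'   present in the data.
#' @examples
#' d <- simulate_occu(default_config(), seed = 1)
#' detection_summary(d)
#' @export
detection_summary <- function(data) {
  stopifnot(inherits(data, "occu_data"))
  Y <- detection_matrix(data)
  det <- apply(Y, 1L, function(r) any(r == 1, na.rm = TRUE))
  allmiss <- apply(Y, 1L, function(r) all(is.na(r)))
  hab <- droplevels(data$sites$habitat)
  out <- data.frame(
    habitat = levels(hab),
    sites = as.integer(table(hab)),
    detected = as.integer(tapply(det, hab, sum)),
    all_missing = as.integer(tapply(allmiss, hab, sum)),
    stringsAsFactors = FALSE
  )
  out$naive <- out$detected / out$sites
  out
}

# logical vector: site had >= 1 detection
site_detected <- function(data) {
  apply(detection_matrix(data), 1L, function(r) any(r == 1, na.rm = TRUE))
}
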