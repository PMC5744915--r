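#' Construct a LandmarkSet
#'
#' @param coords numeric \code{k x 2 x n} array (a single \code{k x 2}
#'   matrix is promoted to n = 1).
#' @param specimenID character length n; defaults to \code{spec1..specn}.
#' @param taxon character length n; defaults to \code{specimenID}.
#' @param roles character length k of \code{"fixed"} / \code{"semilandmark"};
#'   defaults to all fixed, or to [opercleRoles()] when k = 18.
#' @param side character length n in \code{c("left","right","unknown")}.
#' @return a [LandmarkSet-class].
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
#' landmarkSet(sq, specimenID = "sq", roles = rep("fixed", 4))
#' @export
landmarkSet <- function(coords, specimenID = NULL, taxon = NULL,
                        roles = NULL, side = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  n <- dim(coords)[3]; k <- dim(coords)[1]
  if (is.null(specimenID)) specimenID <- paste0("spec", seq_len(n))
  if (is.null(taxon)) taxon <- specimenID
  if (is.null(roles))
    roles <- if (k == 18L) opercleRoles() else rep("fixed", k)
  if (is.null(side)) side <- rep("unknown", n)
  new("LandmarkSet", coords = coords, specimenID = as.character(specimenID),
      taxon = as.character(taxon), roles = roles, side = side)
}

#' Landmark roles of the 18-point opercle scheme
#'
#' Four fixed landmarks -- the joint-associated point (1), the socket of
#' the ball-and-socket joint with the hyomandibula (2), the ventral apex
#' (6) and the posterior apex (12) -- with 14 semilandmarks spaced along
#' the bone edge between them.
#'
#' @return character vector of length 18.
#' @export
opercleRoles <- function() {
  roles <- rep("semilandmark", 18L)
  roles[c(1L, 2L, 6L, 12L)] <- "fixed"
  roles
}

#' Read landmark configurations from a TPS file
#'
#' Parses the record format written by tpsDig: an \code{LM=k} line, k
#' coordinate lines, and optional \code{IMAGE=}, \code{ID=} and
#' \code{SCALE=} lines. \code{SCALE=} values multiply the record's
#' coordinates. The specimen identifier is taken from \code{ID=}, falling
#' back to \code{IMAGE=} (extension stripped) and then to the record number;
#' the taxon defaults to the specimen identifier.
#'
#' @param path file path.
#' @param roles optional per-landmark role vector (see [landmarkSet()]).
#' @return a [LandmarkSet-class].
#' @seealso [writeTPS()], [readLandmarkCSV()]
#' @export
readTPS <- function(path, roles = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- vector("list", length(starts))
  ids <- character(length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    body <- block[-1]
    iskey <- grepl("^[A-Za-z]+\\s*=", body)
    coordLines <- body[!iskey]
    if (length(coordLines) != k)
      stop("malformed TPS record ", r, ": LM=", k, " but ",
           length(coordLines), " coordinate lines")
    xy <- do.call(rbind, lapply(strsplit(coordLines, "[,[:space:]]+"),
                                function(v) {
      v <- as.numeric(v)
      if (length(v) != 2L || any(!is.finite(v)))
        stop("malformed coordinate line in TPS record ", r)
      v
    }))
    keys <- body[iskey]
    getKey <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), keys, ignore.case = TRUE,
                  value = TRUE)
      if (length(hit)) sub("^[A-Za-z]+\\s*=\\s*", "", hit[1]) else NA_character_
    }
    scale <- suppressWarnings(as.numeric(getKey("SCALE")))
    if (!is.na(scale)) xy <- xy * scale
    id <- getKey("ID")
    if (is.na(id)) {
      img <- getKey("IMAGE")
      id <- if (!is.na(img)) sub("\\.[A-Za-z0-9]+$", "", basename(img))
            else paste0("record", r)
    }
    recs[[r]] <- xy
    ids[r] <- id
  }
  ks <- vapply(recs, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("inconsistent landmark counts across TPS records: ",
         paste(unique(ks), collapse = ", "))
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  coords <- array(unlist(recs), c(ks[1], 2L, length(recs)))
  landmarkSet(coords, specimenID = ids, roles = roles)
}

#' Write a LandmarkSet as a TPS file
#'
#' @param x a [LandmarkSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTPS <- function(x, path) {
  k <- nLandmarks(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nSpecimens(x))) {
    writeLines(paste0("LM=", k), con)
    xy <- x@coords[, , i]
    writeLines(sprintf("%.12g %.12g", xy[, 1], xy[, 2]), con)
    writeLines(paste0("ID=", x@specimenID[i]), con)
  }
  invisible(path)
}

#' Read/write landmark configurations as CSV
#'
#' One row per specimen with columns \code{specimen_id, taxon, side,
#' x1, y1, ..., xk, yk}.
#'
#' @param path file path.
#' @param roles optional per-landmark role vector.
#' @return [readLandmarkCSV()]: a [LandmarkSet-class].
#' @export
readLandmarkCSV <- function(path, roles = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("specimen_id", "taxon", "side")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  cc <- setdiff(names(df), need)
  if (length(cc) %% 2L != 0L) stop("odd number of coordinate columns")
  k <- length(cc) %/% 2L
  m <- as.matrix(df[, cc])
  coords <- array(0, c(k, 2L, nrow(df)))
  for (i in seq_len(nrow(df)))
    coords[, , i] <- matrix(m[i, ], k, 2L, byrow = TRUE)
  landmarkSet(coords, specimenID = df$specimen_id, taxon = df$taxon,
              roles = roles, side = df$side)
}

#' @rdname readLandmarkCSV
#' @param x a [LandmarkSet-class] (or [AlignedShapes-class]).
#' @export
writeLandmarkCSV <- function(x, path) {
  k <- nLandmarks(x)
  flat <- t(apply(x@coords, 3, function(m) as.vector(t(m))))
  colnames(flat) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  df <- data.frame(specimen_id = x@specimenID, taxon = x@taxon,
                   side = x@side, flat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
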