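#' Read a two-file backcross ("csvs" dialect)
#'
#' Genotype file layout: first row \code{id} plus marker names; second row
#' blank id plus chromosome of each marker; third row blank id plus cM
#' position; then one row per individual with genotype codes (\code{AA};
#' \code{AB} or \code{H}; \code{-}/\code{NA}/empty = missing). Phenotype
#' file: header with \code{id}, covariates and phenotype columns, one row per
#' individual; rows are matched to the genotype file by id.
#'
#' @param geno_path,pheno_path file paths.
#' @return a \code{bc_cross}; phenotype columns are kept in
#'   \code{pheno$table}, with landmark coordinate columns (named like
#'   \code{<label>.x}) also exposed as \code{pheno$shapes} when present.
#' @export
read_cross_csv <- function(geno_path, pheno_path) {
  raw <- utils::read.csv(geno_path, header = FALSE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(raw) < 4L) stop("malformed genotype file: need 3 header rows + data")
  markers <- as.character(raw[1L, -1L])
  chrs <- as.character(raw[2L, -1L])
  pos <- suppressWarnings(as.numeric(raw[3L, -1L]))
  if (tolower(raw[1L, 1L]) != "id") stop("malformed header: first column must be 'id'")
  if (any(is.na(pos))) stop("malformed position header row")
  ids <- as.character(raw[-(1:3), 1L])
  codes <- as.matrix(raw[-(1:3), -1L, drop = FALSE])
  geno_num <- matrix(NA_integer_, nrow(codes), ncol(codes))
  for (j in seq_len(ncol(codes))) {
    v <- trimws(codes[, j])
    g <- ifelse(v %in% c("AA", "A"), 0L,
                ifelse(v %in% c("AB", "H"), 1L,
                       ifelse(v %in% c("-", "", "NA"), NA_integer_, -9L)))
    bad <- which(!is.na(g) & g == -9L)
    if (length(bad))
      stop(sprintf("unknown genotype code '%s' at line %d, marker %s",
                   v[bad[1L]], bad[1L] + 3L, markers[j]))
    geno_num[, j] <- g
  }
  map <- list(); geno <- list()
  for (ch in unique(chrs)) {
    sel <- which(chrs == ch)
    sel <- sel[order(pos[sel])]
    mp <- pos[sel]; names(mp) <- markers[sel]
    map[[ch]] <- mp
    g <- geno_num[, sel, drop = FALSE]
    colnames(g) <- markers[sel]
    geno[[ch]] <- g
  }
  ph <- utils::read.csv(pheno_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(ph)) stop("phenotype file needs an 'id' column")
  mi <- match(ids, as.character(ph$id))
  if (anyNA(mi)) stop("id mismatch between genotype and phenotype files: ",
                      paste(utils::head(ids[is.na(mi)], 3L), collapse = ", "))
  ph <- ph[mi, , drop = FALSE]
  cov_cols <- intersect(c("logCS", "sex", "cross_direction"), names(ph))
  coord_cols <- grep("\\.(x|y|z)$", names(ph), value = TRUE)
  pheno <- list(table = ph,
                covariates = ph[, c("id", cov_cols), drop = FALSE])
  labs <- unique(sub("\\.(x|y|z)$", "", coord_cols))
  if (length(labs) >= 3L) {
    dims <- c("x", "y", "z")
    d <- sum(paste0(labs[1L], ".", dims) %in% coord_cols)
    k <- length(labs)
    arr <- array(0, c(k, d, nrow(ph)))
    for (li in seq_len(k)) for (di in seq_len(d))
      arr[li, di, ] <- ph[[paste0(labs[li], ".", dims[di])]]
    pheno$shapes <- landmark_sample(arr, labels = labs, ids = as.character(ph$id))
  }
  structure(list(map = structure(map, class = "genetic_map"), geno = geno,
                 truth = NULL, pheno = pheno),
            class = "bc_cross")
}

#' Write a backcross to the two-file CSV dialect
#'
#' Inverse of \code{\link{read_cross_csv}}; round-trips generated data
#' bit-exactly (numeric phenotypes are written with full precision).
#'
#' @param cross a \code{bc_cross} with phenotypes from
#'   \code{\link{simulate_shapes}} or a \code{pheno$table}.
#' @param geno_path,pheno_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cross_csv <- function(cross, geno_path, pheno_path) {
  markers <- unlist(lapply(cross$map, names), use.names = FALSE)
  chrs <- rep(names(cross$map), vapply(cross$map, length, 0L))
  pos <- unlist(cross$map, use.names = FALSE)
  G <- do.call(cbind, cross$geno)
  codes <- matrix("-", nrow(G), ncol(G))
  codes[!is.na(G) & G == 0L] <- "AA"
  codes[!is.na(G) & G == 1L] <- "AB"
  if (!is.null(cross$pheno$covariates)) ids <- cross$pheno$covariates$id
  else ids <- sprintf("ind%04d", seq_len(nrow(G)))
  header <- rbind(c("id", markers), c("", chrs), c("", format(pos, digits = 15L)))
  body <- cbind(ids, codes)
  utils::write.table(rbind(header, body), geno_path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  ## phenotype table: covariates + vectorized raw landmark coordinates
  if (!is.null(cross$pheno$table)) {
    ph <- cross$pheno$table
  } else {
    ph <- cross$pheno$covariates
    shp <- cross$pheno$shapes
    k <- dim(shp)[1L]; d <- dim(shp)[2L]
    dims <- c("x", "y", "z")[seq_len(d)]
    labs <- attr(shp, "labels")
    for (li in seq_len(k)) for (di in seq_len(d))
      ph[[paste0(labs[li], ".", dims[di])]] <- shp[li, di, ]
  }
  utils::write.csv(format(ph, digits = 17L), pheno_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(geno_path, pheno_path))
}

#' Read/write landmark coordinate CSVs
#'
#' One row per specimen (column \code{id}), coordinate columns named
#' \code{<label>.x}, \code{<label>.y}(, \code{<label>.z}).
#'
#' @param path file path.
#' @return a \code{landmark_sample}.
#' @export
read_landmarks_csv <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  coord_cols <- grep("\\.(x|y|z)$", names(ph), value = TRUE)
  if (!length(coord_cols)) stop("no coordinate columns found")
  labs <- unique(sub("\\.(x|y|z)$", "", coord_cols))
  dims <- c("x", "y", "z")
  d <- sum(paste0(labs[1L], ".", dims) %in% coord_cols)
  k <- length(labs)
  arr <- array(0, c(k, d, nrow(ph)))
  for (li in seq_len(k)) for (di in seq_len(d))
    arr[li, di, ] <- ph[[paste0(labs[li], ".", dims[di])]]
  ids <- if ("id" %in% names(ph)) as.character(ph$id) else NULL
  landmark_sample(arr, labels = labs, ids = ids)
}

#' @rdname read_landmarks_csv
#' @param sample a \code{landmark_sample}.
#' @export
write_landmarks_csv <- function(sample, path) {
  k <- dim(sample)[1L]; d <- dim(sample)[2L]
  dims <- c("x", "y", "z")[seq_len(d)]
  labs <- attr(sample, "labels")
  out <- data.frame(id = attr(sample, "ids"), stringsAsFactors = FALSE)
  for (li in seq_len(k)) for (di in seq_len(d))
    out[[paste0(labs[li], ".", dims[di])]] <- sample[li, di, ]
  utils::write.csv(format(out, digits = 17L), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the TPS landmark file dialect
#'
#' Blocks of \code{LM=k} (2D) or \code{LM3=k} (3D) followed by k coordinate
#' lines, with optional \code{ID=} lines per specimen.
#'
#' @param path file path.
#' @return a \code{landmark_sample}.
#' @export
read_tps_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  specs <- list(); ids <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    hd <- toupper(trimws(lines[i]))
    if (!grepl("^LM3?=", hd)) stop("expected LM=/LM3= header at line ", i)
    k <- as.integer(sub("^LM3?=", "", hd))
    d <- if (startsWith(hd, "LM3=")) 3L else 2L
    coords <- matrix(0, k, d)
    for (r in seq_len(k)) {
      coords[r, ] <- as.numeric(strsplit(trimws(lines[i + r]), "\\s+")[[1L]])[seq_len(d)]
    }
    i <- i + k + 1L
    id <- sprintf("spec%d", length(specs) + 1L)
    if (i <= length(lines) && grepl("^ID=", toupper(trimws(lines[i])))) {
      id <- sub("^ID=", "", trimws(lines[i]), ignore.case = TRUE)
      i <- i + 1L
    }
    specs[[length(specs) + 1L]] <- coords
    ids <- c(ids, id)
  }
  k <- nrow(specs[[1L]]); d <- ncol(specs[[1L]])
  arr <- array(unlist(specs), c(k, d, length(specs)))
  landmark_sample(arr, ids = ids)
}

#' @rdname read_tps_file
#' @param sample a \code{landmark_sample}.
#' @export
write_tps_file <- function(sample, path) {
  k <- dim(sample)[1L]; d <- dim(sample)[2L]; n <- dim(sample)[3L]
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("%s=%d", if (d == 3L) "LM3" else "LM", k), con)
    apply(sample[, , i], 1L, function(row)
      writeLines(paste(format(row, digits = 17L), collapse = " "), con))
    writeLines(paste0("ID=", attr(sample, "ids")[i]), con)
  }
  invisible(path)
}

#' Read/write ASCII PLY meshes
#'
#' @param path file path.
#' @return a \code{tri_mesh}.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (tolower(trimws(lines[1L])) != "ply") stop("not a PLY file")
  nv <- nf <- NA_integer_; end_hdr <- NA_integer_
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (grepl("^element vertex", l)) nv <- as.integer(strsplit(l, "\\s+")[[1L]][3L])
    if (grepl("^element face", l)) nf <- as.integer(strsplit(l, "\\s+")[[1L]][3L])
    if (l == "end_header") { end_hdr <- i; break }
  }
  if (anyNA(c(nv, nf, end_hdr))) stop("malformed PLY header")
  vtx <- t(vapply(lines[end_hdr + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][1:3]), numeric(3L)))
  fc <- t(vapply(lines[end_hdr + nv + seq_len(nf)], function(l) {
    p <- as.integer(strsplit(trimws(l), "\\s+")[[1L]])
    if (p[1L] != 3L) stop("only triangle faces supported")
    p[2:4] + 1L
  }, integer(3L)))
  rownames(vtx) <- NULL; rownames(fc) <- NULL
  tri_mesh(vtx, fc)
}

#' @rdname read_ply
#' @param mesh a \code{tri_mesh}.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, digits = 10L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write Wavefront OBJ meshes (triangles only)
#'
#' @param path file path.
#' @return a \code{tri_mesh}.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vtx <- t(vapply(vl, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]][2:4]),
                  numeric(3L)))
  fc <- t(vapply(fl, function(l) {
    p <- strsplit(trimws(l), "\\s+")[[1L]][2:4]
    as.integer(vapply(strsplit(p, "/"), `[`, "", 1L))
  }, integer(3L)))
  rownames(vtx) <- NULL; rownames(fc) <- NULL
  tri_mesh(vtx, fc)
}

#' @rdname read_obj
#' @param mesh a \code{tri_mesh}.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
  invisible(path)
}
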