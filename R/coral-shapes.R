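# Parametric triangulated coral colony shapes. These are morphological
# proxies, not photogrammetric reconstructions: a tabular plate for
# Acropora, a corrugated (branching-proxy) dome for Pocillopora and a
# smooth hemispheroid for Porites, chosen so that the per-taxon rumple
# ordering Pocillopora > Acropora > Porites holds under the defaults.

#' Generate a triangulated coral colony shape
#'
#' Builds a watertight-top triangulated surface whose axis-aligned bounding
#' box matches (`width`, `length`, `height`). The taxon selects the shape
#' family: tabular plate (`Acropora`), corrugated dome (`Pocillopora`),
#' smooth hemispheroid (`Porites`). A seed controls small deterministic
#' shape jitter so that a bank of distinct colonies can be generated.
#'
#' @param taxon One of `"Acropora"`, `"Pocillopora"`, `"Porites"`.
#' @param width,length,height Colony dimensions (m), all positive.
#' @param seed Integer seed.
#' @param resolution Radial/angular mesh resolution.
#' @param corrugation Relative amplitude of the Pocillopora corrugation.
#' @return Object of class `coral_mesh`: list with `vertices` (n x 3),
#'   `faces` (m x 3, 1-based), `taxon`, `dims`.
#' @export
generate_coral_shape <- function(taxon = c("Porites", "Acropora",
                                           "Pocillopora"),
                                 width, length, height, seed = 1,
                                 resolution = 24, corrugation = 0.7) {
  taxon <- match.arg(taxon)
  stopifnot_positive(c(width, length, height), "dimensions")
  set.seed(seed)
  nr <- resolution
  nt <- 2 * resolution
  theta <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
  r <- seq(0, 1, length.out = nr + 1)

  n_lobe <- sample(8:12, 1)
  ph_lobe <- runif(1, 0, 2 * pi)
  n_ring <- sample(3:5, 1)

  zfun <- switch(taxon,
    Porites = function(rr, th) sqrt(pmax(1 - rr^2, 0)),
    Acropora = function(rr, th) {
      # domed plate; the skirt below is added separately
      0.92 + 0.08 * (1 - rr^2)
    },
    Pocillopora = function(rr, th) {
      dome <- sqrt(pmax(1 - rr^2, 0))
      bump <- 0.5 + 0.5 * cos(n_lobe * th + ph_lobe) * cos(2 * pi * n_ring * rr)
      fine <- 0.5 + 0.5 * cos(2.6 * n_lobe * th - ph_lobe) *
        cos(2 * pi * 2.3 * n_ring * rr + ph_lobe)
      dome * (1 - corrugation + corrugation * (0.65 * bump + 0.35 * fine))
    })

  rx <- width / 2
  ry <- length / 2
  verts <- list()
  for (i in seq_along(r)) {
    rr <- r[i]
    z <- zfun(rr, theta)
    verts[[i]] <- cbind(rx * rr * cos(theta), ry * rr * sin(theta), z)
  }
  V <- do.call(rbind, verts)
  # collapse the centre ring to a single apex vertex
  apex <- c(0, 0, zfun(0, 0))
  V[seq_len(nt), ] <- matrix(apex, nt, 3, byrow = TRUE)

  faces <- list()
  nf <- 0
  idx <- function(i, j) (i - 1) * nt + ((j - 1) %% nt) + 1
  for (i in seq_len(nr)) {
    for (j in seq_len(nt)) {
      nf <- nf + 1
      faces[[nf]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      if (i > 1) {
        nf <- nf + 1
        faces[[nf]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
      }
    }
  }
  F <- do.call(rbind, faces)

  if (taxon == "Acropora") {
    # vertical skirt from the plate rim down to the substrate
    rim <- (nr) * nt + seq_len(nt)
    base <- V[rim, ]
    base[, 3] <- 0
    V <- rbind(V, base)
    nb <- nrow(V) - nt
    for (j in seq_len(nt)) {
      j2 <- (j %% nt) + 1
      faces_sk <- rbind(c(rim[j], nb + j, nb + j2),
                        c(rim[j], nb + j2, rim[j2]))
      F <- rbind(F, faces_sk)
    }
  }

  # normalise height so that the bounding box matches exactly
  zmax <- max(V[, 3])
  V[, 3] <- V[, 3] * height / zmax
  structure(list(vertices = V, faces = F, taxon = taxon,
                 dims = c(width = width, length = length, height = height)),
            class = "coral_mesh")
}

#' @export
print.coral_mesh <- function(x, ...) {
  cat(sprintf("coral_mesh: %s, %.2f x %.2f x %.2f m, %d vertices, %d faces\n",
              x$taxon, x$dims[1], x$dims[2], x$dims[3],
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Total 3D surface area of a triangulated mesh
#' @param mesh A `coral_mesh` (or any list with `vertices`, `faces`).
#' @return Area (m^2).
#' @export
mesh_surface_area <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  u <- B - A
  v <- C - A
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

# planar (projected) area: sum of |z components| of face normals / 2
mesh_planar_area <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  u <- B - A
  v <- C - A
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(0.5 * abs(cz))
}

mesh_bbox <- function(mesh) {
  apply(mesh$vertices, 2, range)
}

# densified point cloud: subdivide each triangle so that point spacing is
# at most `spacing` (used for height-field rasterization)
mesh_points <- function(mesh, spacing) {
  V <- mesh$vertices
  F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  e1 <- sqrt(rowSums((B - A)^2))
  e2 <- sqrt(rowSums((C - A)^2))
  e3 <- sqrt(rowSums((C - B)^2))
  m <- pmin(pmax(ceiling(pmax(e1, e2, e3) / spacing), 1), 24)
  out <- vector("list", length(unique(m)))
  kk <- 0
  for (mm in sort(unique(m))) {
    sel <- which(m == mm)
    bc <- expand.grid(i = 0:mm, j = 0:mm)
    bc <- bc[bc$i + bc$j <= mm, ]
    u <- bc$i / mm
    v <- bc$j / mm
    nf <- length(sel)
    np <- length(u)
    Af <- A[sel, , drop = FALSE]
    Uf <- B[sel, , drop = FALSE] - Af
    Vf <- C[sel, , drop = FALSE] - Af
    pts <- matrix(0, nf * np, 3)
    for (d in 1:3) {
      pts[, d] <- rep(Af[, d], each = np) +
        rep(Uf[, d], each = np) * rep(u, nf) +
        rep(Vf[, d], each = np) * rep(v, nf)
    }
    kk <- kk + 1
    out[[kk]] <- pts
  }
  do.call(rbind, out[seq_len(kk)])
}

# scale a mesh to given dims, rotate about z, translate
transform_mesh <- function(mesh, width, length, height, rotation = 0,
                           x = 0, y = 0, z = 0) {
  V <- mesh$vertices
  s <- c(width / mesh$dims[1], length / mesh$dims[2], height / mesh$dims[3])
  V <- sweep(V, 2, s, `*`)
  cr <- cos(rotation)
  sr <- sin(rotation)
  V2 <- V
  V2[, 1] <- cr * V[, 1] - sr * V[, 2] + x
  V2[, 2] <- sr * V[, 1] + cr * V[, 2] + y
  V2[, 3] <- V[, 3] + z
  out <- mesh
  out$vertices <- V2
  out$dims <- c(width = width, length = length, height = height)
  out
}

#' Generate a bank of coral shapes
#'
#' @param n_per_taxon Number of distinct colony models per taxon.
#' @param seed Integer seed.
#' @param resolution Mesh resolution.
#' @return List of class `shape_bank`: `meshes` (named list of
#'   `coral_mesh`), `manifest` (data frame: taxon, id, native bbox).
#' @export
default_shape_bank <- function(n_per_taxon = 10, seed = 1, resolution = 20) {
  taxa <- c("Acropora", "Pocillopora", "Porites")
  meshes <- list()
  man <- list()
  k <- 0
  for (tx in taxa) {
    for (i in seq_len(n_per_taxon)) {
      k <- k + 1
      s <- fan_seed(seed, k)
      m <- generate_coral_shape(tx, width = 1, length = 1, height = 0.5,
                                seed = s, resolution = resolution)
      id <- sprintf("%s_%02d", tolower(tx), i)
      meshes[[id]] <- m
      man[[k]] <- data.frame(taxon = tx, id = id,
                             width = 1, length = 1, height = 0.5)
    }
  }
  structure(list(meshes = meshes, manifest = do.call(rbind, man)),
            class = "shape_bank")
}

#' Write a mesh as Wavefront OBJ
#' @param mesh A `coral_mesh`.
#' @param path Output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#' @param path OBJ file (triangular faces).
#' @param taxon Optional taxon tag.
#' @return A `coral_mesh`.
#' @export
read_obj <- function(path, taxon = NA_character_) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) {
    as.integer(sub("/.*", "", p[2:4]))
  }))
  dims <- apply(V, 2, function(c) diff(range(c)))
  structure(list(vertices = V, faces = F, taxon = taxon,
                 dims = c(width = dims[1], length = dims[2],
                          height = max(V[, 3]))),
            class = "coral_mesh")
}

#' Write a shape bank to a directory (OBJ meshes + manifest CSV)
#' @param bank A `shape_bank`.
#' @param dir Output directory.
#' @export
write_shape_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- bank$manifest
  man$file <- paste0(man$id, ".obj")
  for (i in seq_len(nrow(man))) {
    write_obj(bank$meshes[[man$id[i]]], file.path(dir, man$file[i]))
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a shape bank from a directory
#' @param dir Directory with `manifest.csv` and OBJ files.
#' @return A `shape_bank`.
#' @export
read_shape_bank <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  meshes <- list()
  for (i in seq_len(nrow(man))) {
    meshes[[man$id[i]]] <- read_obj(file.path(dir, man$file[i]),
                                    taxon = man$taxon[i])
  }
  structure(list(meshes = meshes, manifest = man), class = "shape_bank")
}
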