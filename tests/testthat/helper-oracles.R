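# Brute-force isocontour oracle: threshold the whole image, build the voxel
# adjacency graph with igraph, and return the component containing the seed.
# Deliberately independent of the package's flood-fill path.
oracle_isocontour <- function(values, threshold_fraction, seed_ijk,
                              connectivity = 26) {
  dm <- dim(values)
  cutoff <- threshold_fraction * max(values)
  member <- which(values >= cutoff)
  seed_lin <- seed_ijk[1] + dm[1] * ((seed_ijk[2] - 1) +
                                       dm[2] * (seed_ijk[3] - 1))
  if (!(seed_lin %in% member)) stop("oracle: seed below threshold")
  coords <- arrayInd(member, dm)
  m <- length(member)
  adj <- matrix(FALSE, m, m)
  for (a in 1:3) {
    d <- abs(outer(coords[, a], coords[, a], "-"))
    adj <- if (a == 1) d else pmax(adj, d)  # chebyshev for 26-connectivity
  }
  if (connectivity == 6) {
    man <- 0
    for (a in 1:3) man <- man + abs(outer(coords[, a], coords[, a], "-"))
    edges <- which(man == 1, arr.ind = TRUE)
  } else {
    edges <- which(adj == 1, arr.ind = TRUE)
  }
  g <- igraph::graph_from_edgelist(edges[edges[, 1] < edges[, 2], ,
                                         drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, m - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sort(member[comp == comp[match(seed_lin, member)]])
}

random_activity_image <- function(dm, voxel_size = c(1, 1, 1), max_val = 9) {
  vals <- array(sample(0:max_val, prod(dm), replace = TRUE), dim = dm)
  activity_image(vals, voxel_size)
}

# single blurred hot sphere in a warm background, for fitting tests
blurred_sphere_fixture <- function(ratio = 6, radius_mm = 23.58,
                                   fwhm = 15, noise = FALSE, seed = 1,
                                   grid = c(48L, 48L, 48L), vox = c(4, 4, 4)) {
  ctr <- grid * vox / 2
  bg <- geometric_object("cylinder", ctr, c(80, 170), 1, "bg")
  sph <- geometric_object("sphere", ctr, radius_mm, ratio, "sph")
  ras <- rasterize(phantom_spec(list(bg, sph), grid_shape = grid,
                                voxel_size = vox))
  img <- degrade(ras$image, acquisition_model(fwhm, 2e6, noise, seed))
  list(image = img, mask = ras$masks$sph, clean = ras$image,
       center = as.integer(ceiling(ctr / vox)))
}
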