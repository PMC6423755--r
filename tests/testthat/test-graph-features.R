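test_that("a regular grid yields congruent Voronoi cells with zero disorder", {
  g <- as.matrix(expand.grid(x = seq(10, 50, 10), y = seq(10, 50, 10)))
  v <- voronoi_features(g, bbox = c(5, 55, 5, 55))
  expect_length(v, 12)
  expect_identical(names(v), nucmorph:::voronoi_feature_names())
  expect_equal(unname(v["voronoi:area:average"]), 100, tolerance = 1e-9)
  for (a in c("perimeter", "chord", "area")) {
    expect_equal(unname(v[paste0("voronoi:", a, ":sd")]), 0,
                 tolerance = 1e-9)
    expect_equal(unname(v[paste0("voronoi:", a, ":disorder")]), 0,
                 tolerance = 1e-9)
    expect_equal(unname(v[paste0("voronoi:", a, ":minmax_ratio")]), 1,
                 tolerance = 1e-9)
  }
  expect_error(voronoi_features(cbind(1:10, 2 * (1:10) + 3)), "collinear")
})

test_that("Voronoi aggregates match an independent geometry oracle", {
  set.seed(20)
  p <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  bbox <- c(0, 100, 0, 100)
  v <- voronoi_features(p, bbox = bbox)

  csv <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".json")
  write.csv(data.frame(x = p[, 1], y = p[, 2]), csv, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, csv",
    "import numpy as np",
    "from shapely.geometry import MultiPoint, Point, box",
    "from shapely.ops import voronoi_diagram",
    "pts = np.loadtxt(sys.argv[1], delimiter=',', skiprows=1)",
    "cells = voronoi_diagram(MultiPoint([tuple(q) for q in pts]))",
    "clip = box(0, 0, 100, 100)",
    "areas, perims = [], []",
    "for q in pts:",
    "    for c in cells.geoms:",
    "        if c.contains(Point(q)):",
    "            cc = c.intersection(clip)",
    "            areas.append(cc.area); perims.append(cc.length)",
    "            break",
    "def agg(v):",
    "    v = np.asarray(v); s = v.std(ddof=1); m = v.mean()",
    "    return dict(average=m, sd=s, minmax=v.min()/v.max(),",
    "                disorder=1 - 1/(1 + s/m))",
    "json.dump(dict(area=agg(areas), perimeter=agg(perims),",
    "               n=len(areas)), open(sys.argv[2], 'w'))"), script)
  res <- system2("python", c(script, csv, out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out) && file.size(out) > 0,
              label = paste("geometry oracle ran:", paste(res, collapse = " ")))
  o <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(o$n, 20)
  expect_equal(unname(v["voronoi:area:average"]), o$area$average,
               tolerance = 1e-6)
  expect_equal(unname(v["voronoi:area:sd"]), o$area$sd, tolerance = 1e-6)
  expect_equal(unname(v["voronoi:area:minmax_ratio"]), o$area$minmax,
               tolerance = 1e-6)
  expect_equal(unname(v["voronoi:area:disorder"]), o$area$disorder,
               tolerance = 1e-6)
  expect_equal(unname(v["voronoi:perimeter:average"]), o$perimeter$average,
               tolerance = 1e-6)
  expect_equal(unname(v["voronoi:perimeter:sd"]), o$perimeter$sd,
               tolerance = 1e-6)
  expect_equal(unname(v["voronoi:perimeter:disorder"]),
               o$perimeter$disorder, tolerance = 1e-6)
})

test_that("Delaunay features are analytic on simple configurations", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  d <- delaunay_features(tri)
  expect_length(d, 8)
  expect_identical(names(d), nucmorph:::delaunay_feature_names())
  expect_equal(unname(d["delaunay:side_length:mean"]), 1, tolerance = 1e-9)
  expect_equal(unname(d["delaunay:side_length:sd"]), 0, tolerance = 1e-9)
  expect_equal(unname(d["delaunay:side_length:disorder"]), 0,
               tolerance = 1e-9)
  expect_equal(unname(d["delaunay:triangle_area:mean"]), sqrt(3) / 4,
               tolerance = 1e-9)

  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ds <- delaunay_features(sq)
  lens <- c(1, 1, 1, 1, sqrt(2))       # 4 sides + 1 diagonal
  expect_equal(unname(ds["delaunay:side_length:mean"]), mean(lens),
               tolerance = 1e-9)
  expect_equal(unname(ds["delaunay:side_length:sd"]), sd(lens),
               tolerance = 1e-9)
  expect_equal(unname(ds["delaunay:side_length:minmax_ratio"]),
               1 / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(ds["delaunay:triangle_area:mean"]), 0.5,
               tolerance = 1e-9)
  expect_error(delaunay_features(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("Delaunay edges match the scipy triangulation oracle", {
  set.seed(21)
  p <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  d <- delaunay_features(p)
  csv <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".json")
  write.csv(data.frame(x = p[, 1], y = p[, 2]), csv, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import numpy as np",
    "from scipy.spatial import Delaunay",
    "pts = np.loadtxt(sys.argv[1], delimiter=',', skiprows=1)",
    "tr = Delaunay(pts)",
    "edges = set()",
    "areas = []",
    "for s in tr.simplices:",
    "    a, b, c = pts[s[0]], pts[s[1]], pts[s[2]]",
    "    areas.append(abs(np.cross(b - a, c - a)) / 2)",
    "    for i in range(3):",
    "        e = tuple(sorted((s[i], s[(i + 1) % 3])))",
    "        edges.add(e)",
    "lens = [float(np.linalg.norm(pts[i] - pts[j])) for i, j in edges]",
    "json.dump(dict(mean_len=float(np.mean(lens)),",
    "               sd_len=float(np.std(lens, ddof=1)),",
    "               mean_area=float(np.mean(areas)),",
    "               sd_area=float(np.std(areas, ddof=1)),",
    "               n_edges=len(lens)), open(sys.argv[2], 'w'))"), script)
  res <- system2("python", c(script, csv, out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out) && file.size(out) > 0,
              label = paste("geometry oracle ran:", paste(res, collapse = " ")))
  o <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(unname(d["delaunay:side_length:mean"]), o$mean_len,
               tolerance = 1e-6)
  expect_equal(unname(d["delaunay:side_length:sd"]), o$sd_len,
               tolerance = 1e-6)
  expect_equal(unname(d["delaunay:triangle_area:mean"]), o$mean_area,
               tolerance = 1e-6)
  expect_equal(unname(d["delaunay:triangle_area:sd"]), o$sd_area,
               tolerance = 1e-6)
})

test_that("graph aggregates are invariant under rigid motion", {
  set.seed(22)
  p <- cbind(runif(30, 0, 60), runif(30, 0, 60))
  d0 <- delaunay_features(p)
  th <- 0.61
  q <- cbind(p[, 1] * cos(th) - p[, 2] * sin(th) + 15,
             p[, 1] * sin(th) + p[, 2] * cos(th) - 7)
  expect_equal(delaunay_features(q), d0, tolerance = 1e-6)

  # Voronoi: translation, and 90-degree rotation about the window center
  v0 <- voronoi_features(p, bbox = c(0, 60, 0, 60))
  vt <- voronoi_features(cbind(p[, 1] + 11, p[, 2] - 3),
                         bbox = c(11, 71, -3, 57))
  expect_equal(vt, v0, tolerance = 1e-6)
  p90 <- cbind(60 - p[, 2], p[, 1])
  v90 <- voronoi_features(p90, bbox = c(0, 60, 0, 60))
  expect_equal(v90, v0, tolerance = 1e-6)
})

test_that("aligned nuclei give zero orientation entropy and unit energy", {
  set.seed(23)
  df <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100),
                   orientation = 42)
  o <- orientation_features(df)
  expect_length(o, 39)
  expect_identical(names(o), nucmorph:::orientation_feature_names())
  expect_equal(unname(o["orient:entropy:mean"]), 0)
  expect_equal(unname(o["orient:energy:mean"]), 1)
  expect_equal(unname(o["orient:entropy:sd"]), 0)
  expect_equal(unname(o["orient:entropy:range"]), 0)
  expect_equal(unname(o["orient:energy:range"]), 0)
})

test_that("orientation co-occurrence matches a hand-enumerated example", {
  # 5 nuclei on a line with unambiguous 2-nearest-neighbor sets
  df <- data.frame(x = c(0, 1, 2.2, 3.5, 5), y = 0,
                   orientation = c(10, 15, 100, 105, 170))
  B <- 4; k <- 2
  o <- orientation_features(df, k_neighbors = k, b_bins = B)

  # independent enumeration: bins at 45 degrees each
  bins <- floor(df$orientation / 45) + 1          # 1 1 3 3 4
  nbrs <- list(c(2, 3), c(1, 3), c(2, 4), c(3, 5), c(4, 3))
  per <- matrix(0, 5, 13)
  for (i in 1:5) {
    M <- matrix(0, B, B)
    for (j in nbrs[[i]]) M[bins[i], bins[j]] <- M[bins[i], bins[j]] + 1
    M <- (M + t(M)) / 2
    P <- M / sum(M)
    px <- rowSums(P); py <- colSums(P)
    ii <- row(P); jj <- col(P)
    ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
    pxmy <- sapply(0:(B - 1), function(kk) sum(P[abs(ii - jj) == kk]))
    pxpy <- sapply(2:(2 * B), function(kk) sum(P[(ii + jj) == kk]))
    ca <- sum((0:(B - 1)) * pxmy); ia <- sum((2:(2 * B)) * pxpy)
    H <- ent(P)
    mux <- sum((1:B) * px); muy <- sum((1:B) * py)
    sdx <- sqrt(sum((1:B)^2 * px) - mux^2)
    sdy <- sqrt(sum((1:B)^2 * py) - muy^2)
    corr <- if (sdx > 1e-12 && sdy > 1e-12)
      (sum(ii * jj * P) - mux * muy) / (sdx * sdy) else 0
    hx <- ent(px); hy <- ent(py)
    pp <- outer(px, py)
    hxy1 <- -sum((P * log2(pp))[P > 0 & pp > 0])
    hxy2 <- ent(pp)
    per[i, ] <- c(sum(P * (ii - jj)^2), sum(P / (1 + (ii - jj)^2)),
                  ca, sum((0:(B - 1) - ca)^2 * pxmy), ent(pxmy),
                  ia, sum((2:(2 * B) - ia)^2 * pxpy), ent(pxpy),
                  H, sum(P^2), corr,
                  if (max(hx, hy) > 1e-12) (H - hxy1) / max(hx, hy) else 0,
                  sqrt(max(0, 1 - exp(-2 * (hxy2 - H)))))
  }
  nm <- nucmorph:::orientation_descriptor_names()
  for (d in seq_along(nm)) {
    v <- per[, d]
    expect_equal(unname(o[paste0("orient:", nm[d], ":mean")]), mean(v),
                 tolerance = 1e-9)
    expect_equal(unname(o[paste0("orient:", nm[d], ":sd")]), sd(v),
                 tolerance = 1e-9)
    expect_equal(unname(o[paste0("orient:", nm[d], ":range")]),
                 max(v) - min(v), tolerance = 1e-9)
  }
})

test_that("undefined orientations are excluded with a warning", {
  df <- data.frame(x = runif(10), y = runif(10),
                   orientation = c(rep(0, 6), 30, 60, 90, 120),
                   orientation_defined = c(rep(FALSE, 6), rep(TRUE, 4)))
  expect_warning(orientation_features(df, k_neighbors = 2), "50%")
  expect_error(
    suppressWarnings(orientation_features(df, k_neighbors = 5)),
    "k_neighbors")
})

test_that("the assembled vector has 189 uniquely named entries", {
  d <- demo_spot()
  fv <- compute_spot_features(d$sim$mask, d$sim$image, spot_id = "a")
  expect_length(fv, 189)
  expect_false(any(duplicated(names(fv))))
  expect_equal(as.vector(table(feature_families())), c(100, 30, 39, 12, 8))

  fv2 <- compute_spot_features(d$sim$mask, d$sim$image, spot_id = "a")
  expect_identical(fv, fv2)

  shp <- fv[1:100]; tex <- fv[101:130]; ori <- fv[131:169]
  vor <- fv[170:181]; del <- fv[182:189]
  expect_equal(
    as.vector(assemble_feature_vector(shp, tex, ori, vor, del)),
    as.vector(fv))
  expect_error(assemble_feature_vector(shp[1:99], tex, ori, vor, del),
               "family shape expected 100")
  expect_error(assemble_feature_vector(shp, tex, ori, vor, del[1:7]),
               "family delaunay expected 8")
})
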