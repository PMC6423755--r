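# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A 320 px spot with 50 well-separated nuclei plus its deconvolution and
# watershed segmentation.
demo_spot <- function() fixture("demo_spot", function() {
  sp <- spot_sim_params(n_nuclei = 50, width = 320, height = 320,
                        clustering = 0, seed = 7)
  sim <- generate_spot_image(sp)
  dec <- color_deconvolve(sim$image)
  seg <- segment_nuclei(dec$hematoxylin)
  list(params = sp, sim = sim, dec = dec, seg = seg)
})

# Records extracted from the ground-truth mask of the demo spot.
demo_records <- function() fixture("demo_records", function() {
  d <- demo_spot()
  extract_nucleus_records(d$sim$mask, d$sim$image)
})

# Regular n-gon approximating a circle/ellipse boundary
ellipse_polygon <- function(cx = 0, cy = 0, a = 1, b = 1, theta_deg = 0,
                            n = 180) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- theta_deg * pi / 180
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(th) - y * sin(th), cy + x * sin(th) + y * cos(th))
}

# Blank white RGB image array
white_image <- function(h = 64, w = 64) array(1, c(h, w, 3))

# Minimal nm_nucleus stand-in carrying only an intensity patch, for
# texture tests with controlled pixel values.
patch_record <- function(patch, interior = NULL) {
  if (is.null(interior)) interior <- matrix(TRUE, nrow(patch), ncol(patch))
  structure(list(patch = list(channels = list(patch, patch, patch),
                              interior = interior)),
            class = "nm_nucleus")
}
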