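## Shared fixtures, built once per test run (all generated in code).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## plain straight tube, radius 15, length 200, no flap
tube_scene <- function() fixture("tube", function()
  make_dissected_aorta(radius = 15, length = 200, arch_radius = 0, taper = 0,
                       flap = NULL, tears = NULL, landmark_arclength = 50,
                       n_axial = 120, n_circ = 64, seed = 1))

tube_structured <- function() fixture("tube_st", function()
  parameterize_surface(tube_scene(), n_layers = 100, n_nodes = 50))

## default dissected aorta (arch + flap + 2 tears + thrombus)
dissected_scene <- function() fixture("dissected", function()
  make_dissected_aorta(seed = 1,
                       thrombus = list(s_range = c(240, 340), frac = 0.6,
                                       thickness = 5)))

dissected_structured <- function() fixture("dissected_st", function()
  parameterize_surface(dissected_scene(), n_layers = 100, n_nodes = 40))

dissected_solid <- function() fixture("dissected_solid", function()
  build_solid_mesh(dissected_scene(), n_circ = 24, n_axial = 32))

dissected_tractions <- function() fixture("dissected_tract", function() {
  sc <- dissected_scene()
  inl <- inlet_from_velocity(radius = 15, flow = 25)
  tun <- tune_total_resistance(sc, inl, target_sbp = 159,
                               structured = dissected_structured())
  map_pressure_to_solid(tun$field, dissected_solid())
})

## thin-cylinder Laplace fixture (r = 14, t = 2, L = 100)
laplace_cylinder <- function() fixture("cyl", function()
  make_cylinder_fixture(r = 14, t = 2, L = 100, n_layers = 4,
                        n_circ = 48, n_axial = 24))

## structured surface built analytically from rings (circular cross
## sections along +z), for exact-value tests
ring_surface <- function(radii, n_nodes = 50, z = NULL, landmark = NULL) {
  nl <- length(radii)
  if (is.null(z)) z <- seq_len(nl)
  th <- 2 * pi * (seq_len(n_nodes) - 1) / n_nodes
  nodes <- array(0, c(nl, n_nodes, 3))
  for (j in seq_len(nl)) {
    nodes[j, , 1] <- radii[j] * cos(th)
    nodes[j, , 2] <- radii[j] * sin(th)
    nodes[j, , 3] <- z[j]
  }
  st <- structure(list(nodes = nodes,
                       layer_centers = cbind(0, 0, z),
                       s = z, n_layers = nl, n_nodes = n_nodes,
                       landmark_layer = landmark %||% NA_integer_),
                  class = "structured_surface")
  st$frames <- local_frames(st)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a
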