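# shared fixtures: built in code, cached across test files in one session

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# Taylor-Green vortex run on a periodic square, returns final state
tg_run <- function(n, dt, t_end, Re = 100, L = 2 * pi) {
  g <- build_grid(list(c(0, L), c(0, L)), list(c(0, L), c(0, L)), L / n)
  sol <- build_solver(g, solver_settings(Re = Re, dt = dt, U_inf = 0,
                                         bc = "periodic"))
  x <- g$axes[[1]]$xc; y <- g$axes[[2]]$xc
  st <- flow_state(g,
                   u = -outer(cos(x), sin(y)),
                   v = outer(sin(x), cos(y)),
                   p = -(outer(cos(2 * x), rep(1, n)) +
                           outer(rep(1, n), cos(2 * y))) / 4)
  for (i in seq_len(round(t_end / dt))) st <- step_flow(sol, st)
  st
}

tg_grid <- function(n, L = 2 * pi) {
  build_grid(list(c(0, L), c(0, L)), list(c(0, L), c(0, L)), L / n)
}

# the desk-scale sweep used by trend tests and acceptance; ~8 min total,
# computed once per test session
desk_sweep <- function() {
  cached("sweep", frequency_sweep(c(0.33, 0.65, 1.30), n_cycles = 4))
}

desk_clip_run <- function() {
  cached("clip65", {
    pf <- wing_planform()
    clipped <- clip_trailing_edge(pf, default_clip_line(pf))
    run_flapping_case(0.65, planform = clipped, n_cycles = 4)
  })
}

desk_body_only <- function() {
  cached("body0", run_flapping_case(0, n_cycles = 6))
}

# cached verification runs shared between the solver tests and acceptance
tg_decay_case <- function() cached("tg_decay", tg_run(64, 0.005, 1))
tg_temporal_cases <- function() {
  cached("tg_temporal", list(tg_run(48, 0.04, 0.4),
                             tg_run(48, 0.02, 0.4),
                             tg_run(48, 0.01, 0.4)))
}
tg_spatial_errors <- function() {
  cached("tg_spatial", sapply(c(24, 48, 96), function(n) {
    st <- tg_run(n, 0.0025, 0.25)
    g <- tg_grid(n)
    uex <- -outer(cos(g$axes[[1]]$xc), sin(g$axes[[2]]$xc)) * exp(-2 * 0.25 / 100)
    sqrt(mean((st$u - uex)^2))
  }))
}

mirror_case <- function() {
  cached("mirror", {
    g <- build_grid(list(c(-3, 5), c(-2, 2)), list(c(-1, 1.5), c(-1, 1)), 0.05)
    sol <- build_solver(g, solver_settings(Re = 100, dt = 0.01))
    body <- ellipse_shape(0.5, 0.2)
    st <- flow_state(g, u = 1)
    for (i in 1:80) st <- step_flow(sol, st, list(body))
    list(state = st, solver = sol, body = body, grid = g)
  })
}

moving_body_divergence <- function() {
  cached("movdiv", {
    g <- build_grid(list(c(-2, 3), c(-1.5, 1.5)),
                    list(c(-0.8, 0.8), c(-0.8, 0.8)), 0.05)
    sol <- build_solver(g, solver_settings(Re = 173, dt = 0.005))
    st <- flow_state(g, u = 1)
    divs <- numeric(40)
    for (i in 1:40) {
      t_new <- st$t + sol$settings$dt
      plate <- plate_shape(0.3, 0.06,
                           center = c(0.3 * sin(2 * pi * t_new), 0),
                           angle = 0.5,
                           vel = c(0.3 * 2 * pi * cos(2 * pi * t_new), 0))
      st <- step_flow(sol, st, list(plate))
      divs[i] <- st$divergence
    }
    list(state = st, divs = divs)
  })
}
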