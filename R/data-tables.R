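# Bundled spray-drying optimization datasets (shipped as plain CSV/YAML
# under inst/extdata and parsed with the package's own readers).

#' Spray-drying optimization screening design (2^3)
#'
#' The first optimization round for PLGA microparticle manufacture: a 2^3
#' full factorial over feed concentration (0.25--0.35 % w/v), nitrogen gas
#' flow rate (600--742 L/h) and aspiration rate (20--30 m^3/min), with the
#' resulting geometric diameter `dg` (um), `gsd_dg`, volume diameter `dv`
#' (um) and `gsd_dv` of each batch as responses.
#'
#' @return `data.frame` with one row per run.
#' @seealso [doe1_factors()], [factorial_design()]
#' @export
doe1_table <- function() {
  utils::read.csv(system.file("extdata", "doe1.csv", package = "aeroperf"),
                  comment.char = "#")
}

#' @rdname doe1_table
#' @export
doe1_factors <- function() {
  data.frame(name = c("feed_conc", "n2_flow", "aspiration"),
             low = c(0.25, 600, 20), high = c(0.35, 742, 30),
             units = c("% w/v", "L/h", "m^3/min"))
}

#' Spray-drying refinement design (2^2)
#'
#' The second optimization round: a 2^2 full factorial over aspiration rate
#' (30--35 m^3/min) and feed flow rate (3.0--7.5 mL/min), same response
#' columns as [doe1_table()].
#'
#' @return `data.frame` with one row per run.
#' @export
doe2_table <- function() {
  utils::read.csv(system.file("extdata", "doe2.csv", package = "aeroperf"),
                  comment.char = "#")
}

#' @rdname doe2_table
#' @export
doe2_factors <- function() {
  data.frame(name = c("aspiration", "feed_rate"),
             low = c(30, 3.0), high = c(35, 7.5),
             units = c("m^3/min", "mL/min"))
}
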