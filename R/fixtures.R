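#' Curated small benchmark instances
#'
#' Hand-written toy instances with known expected outputs, used throughout
#' the documentation and test suite:
#' \describe{
#'   \item{chain}{linear pathway A -> B -> C; seeds \{A\}; scope \{B, C\}.}
#'   \item{blocked}{A + X -> B with X unavailable; scope empty.}
#'   \item{handoff}{pathway split across two organisms (A -> B in m1,
#'     B -> C in m2); C is producible only by the community.}
#'   \item{interchangeable}{a three-step essential chain feeding a final
#'     step carried by either of two producers: 2 minimal communities of
#'     size 4, 3 essential members, one substitutable class of 2.}
#'   \item{enum12}{12 organisms, three target functions each carried by an
#'     interchangeable producer pair plus 6 irrelevant organisms: 8 minimal
#'     communities of size 3, no essential member, three substitutable
#'     classes.}
#' }
#'
#' @return Named list of instances; each holds its inputs (`network` or
#'   `system`, `seeds` / `condition`, `targets` where relevant) and the
#'   expected outputs under `expected`.
#' @export
make_fixture_suite <- function() {
  cond <- function(seeds) seed_condition("fixture_medium", seeds)
  net <- function(id, ...) metabolic_network(id, list(...))

  chain <- list(
    network = net("chain", reaction("r1", "A", "B"), reaction("r2", "B", "C")),
    seeds = "A",
    expected = list(scope = c("B", "C"))
  )

  blocked <- list(
    network = net("blocked", reaction("r1", c("A", "X"), "B")),
    seeds = "A",
    expected = list(scope = character(0))
  )

  handoff <- list(
    system = system_spec("toy", "genome_resolved", list(
      net("m1", reaction("r1", "A", "B")),
      net("m2", reaction("r2", "B", "C"))
    )),
    condition = cond("A"),
    expected = list(
      community_scope = c("B", "C"),
      per_member_scopes = list(m1 = "B", m2 = character(0)),
      cooperation_only = "C",
      mincom = list(targets = "C", k = 2L,
                    solutions = list(c("m1", "m2")))
    )
  )

  interchangeable <- list(
    system = system_spec("toy", "genome_resolved", list(
      net("e1", reaction("r1", "A", "B")),
      net("e2", reaction("r2", "B", "C")),
      net("e3", reaction("r3", "C", "D")),
      net("p1", reaction("r4", "D", "T")),
      net("p2", reaction("r4", "D", "T"))
    )),
    condition = cond("A"),
    targets = "T",
    expected = list(
      k = 4L,
      solutions = list(c("e1", "e2", "e3", "p1"), c("e1", "e2", "e3", "p2")),
      essential = c("e1", "e2", "e3"),
      alternative = c("p1", "p2"),
      substitutable = list(c("p1", "p2"))
    )
  )

  enum_members <- c(
    lapply(1:3, function(i) {
      lapply(c("a", "b"), function(tag)
        net(sprintf("p%d%s", i, tag),
            reaction(sprintf("rt%d", i), "A", sprintf("T%d", i))))
    }),
    list(lapply(1:6, function(i)
      net(sprintf("f%02d", i),
          reaction(sprintf("rf%d", i), "Z", sprintf("W%d", i)))))
  )
  enum12 <- list(
    system = system_spec("toy", "genome_resolved",
                         unlist(enum_members, recursive = FALSE)),
    condition = cond("A"),
    targets = c("T1", "T2", "T3"),
    expected = list(
      k = 3L,
      n_solutions = 8L,
      essential = character(0),
      substitutable = list(c("p1a", "p1b"), c("p2a", "p2b"), c("p3a", "p3b"))
    )
  )

  list(chain = chain, blocked = blocked, handoff = handoff,
       interchangeable = interchangeable, enum12 = enum12)
}
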