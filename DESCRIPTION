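Package: kirchhoffpk
Title: Clearance Composition Calculus for Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composes rate-defining pharmacokinetic processes (clearances and
    first-order rate constants) in parallel and in series, the circuit-style
    calculus in which parallel processes add and in-series processes combine
    harmonically. Provides renal, hepatic (with and without basolateral
    transport) and saturable Michaelis-Menten organ clearance models assembled
    from the calculus alongside their traditional differential-equation
    counterparts, Kp_uu versus hepatic-availability model curves for the
    well-stirred, parallel-tube and extended-clearance models, extravascular
    input algebra (gut clearance, apparent bioavailability, flip-flop
    kinetics, mean residence and absorption times), a closed-form catenary
    metabolite-chain simulator with statistical-moment analysis, a
    noncompartmental analysis toolkit, a seeded fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
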