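Package: dmxr
Title: Decision-Making Expertise Scoring for Arcade-Style Session Logs
Version: 0.1.0
Authors@R:
    person("dmxr", "maintainers", email = "dmxr@example.org", role = c("aut", "cre"))
Description: Scores strategic time-allocation quality in arcade-style
    behavioral sessions. A participant spends a fixed 30-minute budget
    across a 21-game arcade with unknown, heterogeneous ticket rates;
    every second is treated as a decision to stay or switch, valued by
    the tie-averaged profitability rank of the occupied game given only
    what the participant has experienced so far (the DMX score).
    Includes session-log reading and cleaning, total-ticket and
    switching measures, questionnaire scoring (CRT, AOMTB, NCS),
    distributional summaries with (adjusted) coefficients of variation,
    fixed-effect and DerSimonian-Laird meta-analysis of per-study means
    and Fisher-z correlations, an agent-based session and cohort
    simulator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
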