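# Column dialect of the Correlates of War v4.0 files.  Mirrors the
# package defaults; edit a copy to map other dataset versions.
war:
  columns:
    war_id: WarNum
    war_name: WarName
    state_code: ccode
    state_name: StateName
    side: Side
    outcome: Outcome
  start_date: [StartYear1, StartMonth1, StartDay1]
  end_date: [EndYear1, EndMonth1, EndDay1]
  outcome_codes:
    won: [1]
    lost: [2]
    stalemate: [3, 6]
    transformed: [4]
    other: [5, 7, 8]
  sentinels: [-9, -8]
capabilities:
  columns:
    state_code: ccode
    year: year
  measures:
    pec: pec
    milper: milper
    tpop: tpop
    upop: upop
    cinc: cinc
  sentinels: [-9, -8]
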