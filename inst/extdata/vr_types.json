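{
  "DA": "date",
  "DT": "date",
  "IS": "number",
  "DS": "number",
  "US": "number",
  "UL": "number",
  "SS": "number",
  "SL": "number",
  "FL": "number",
  "FD": "number",
  "UI": "text",
  "LO": "text",
  "SH": "text",
  "CS": "text",
  "PN": "text",
  "ST": "text",
  "TM": "text",
  "LT": "text",
  "UT": "text"
}
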