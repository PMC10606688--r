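{
  "DYS19":    [10, 19],
  "DYS389I":  [9, 17],
  "DYS389II": [24, 34],
  "DYS390":   [17, 28],
  "DYS391":   [6, 14],
  "DYS392":   [6, 17],
  "DYS393":   [7, 18],
  "DYS385ab": [7, 25],
  "DYS437":   [13, 17],
  "DYS438":   [6, 14],
  "DYS439":   [8, 15],
  "DYS448":   [17, 24],
  "DYS456":   [13, 18],
  "DYS458":   [13, 20],
  "DYS635":   [17, 27],
  "YGATAH4":  [8, 13],
  "DYS481":   [17, 32],
  "DYS533":   [7, 17],
  "DYS549":   [9, 15],
  "DYS570":   [14, 21],
  "DYS576":   [13, 21],
  "DYS643":   [6, 17],
  "DYS460":   [7, 14]
}
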