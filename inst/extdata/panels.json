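{
  "Minimal": [
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS385ab"
  ],
  "PowerPlexY12": [
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS385ab", "DYS437", "DYS438", "DYS439"
  ],
  "Yfiler": [
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS385ab", "DYS437", "DYS438", "DYS439", "DYS448",
    "DYS456", "DYS458", "DYS635", "YGATAH4"
  ],
  "PowerPlexY23": [
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS385ab", "DYS437", "DYS438", "DYS439", "DYS448",
    "DYS456", "DYS458", "DYS635", "YGATAH4", "DYS481", "DYS533",
    "DYS549", "DYS570", "DYS576", "DYS643"
  ],
  "Microreader24Y": [
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS385ab", "DYS437", "DYS438", "DYS439", "DYS448",
    "DYS456", "DYS458", "DYS635", "YGATAH4", "DYS481", "DYS533",
    "DYS549", "DYS570", "DYS576", "DYS643", "DYS460"
  ]
}
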