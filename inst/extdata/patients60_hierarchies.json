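{
  "Gender": {
    "gender:*": {
      "M": {},
      "F": {}
    }
  },
  "Marriage": {
    "marriage:*": {
      "Single": {},
      "Marriage": {},
      "Divorce": {}
    }
  },
  "Smoke": {
    "smoke:*": {
      "Y": {},
      "N": {}
    }
  },
  "Zip": {
    "zip:*": {
      "322*": {
        "32211": {}
      },
      "325*": {
        "32556": {}
      },
      "326*": {
        "32652": {}
      },
      "327*": {
        "32767": {}
      },
      "328*": {
        "32801": {},
        "32868": {},
        "32855": {}
      },
      "331*": {
        "33102": {}
      },
      "332*": {
        "33218": {}
      },
      "334*": {
        "33451": {}
      },
      "336*": {
        "33613": {},
        "33647": {},
        "33615": {},
        "33650": {},
        "33648": {}
      },
      "337*": {
        "33709": {}
      },
      "343*": {
        "34302": {}
      },
      "345*": {
        "34565": {},
        "34574": {},
        "34543": {}
      },
      "346*": {
        "34660": {}
      },
      "347*": {
        "34768": {}
      },
      "348*": {
        "34813": {}
      },
      "725*": {
        "72512": {}
      },
      "728*": {
        "72868": {}
      },
      "753*": {
        "75384": {}
      },
      "756*": {
        "75677": {},
        "75685": {}
      },
      "758*": {
        "75865": {},
        "75828": {}
      },
      "759*": {
        "75926": {}
      }
    }
  }
}
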