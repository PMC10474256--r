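{
  "nodes": [
    {
      "label": "input_1_1",
      "type": "input",
      "passes": 1,
      "flags": [
        "is_input"
      ],
      "module_addresses": []
    },
    {
      "label": "cos_1_2",
      "type": "cos",
      "passes": 2,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "linear_1_3",
      "type": "linear",
      "passes": 2,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "add_1_4",
      "type": "add",
      "passes": 2,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "sin_1_5",
      "type": "sin",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_6",
      "type": "output",
      "passes": 1,
      "flags": [
        "is_output"
      ],
      "module_addresses": []
    }
  ],
  "edges": [
    {
      "from": "input_1_1",
      "to": "cos_1_2:1",
      "arg": "0"
    },
    {
      "from": "cos_1_2:1",
      "to": "linear_1_3:1",
      "arg": "0"
    },
    {
      "from": "linear_1_3:1",
      "to": "add_1_4:1",
      "arg": "0"
    },
    {
      "from": "add_1_4:1",
      "to": "sin_1_5",
      "arg": "0"
    },
    {
      "from": "sin_1_5",
      "to": "cos_1_2:2",
      "arg": "0"
    },
    {
      "from": "cos_1_2:2",
      "to": "linear_1_3:2",
      "arg": "0"
    },
    {
      "from": "linear_1_3:2",
      "to": "add_1_4:2",
      "arg": "0"
    },
    {
      "from": "add_1_4:2",
      "to": "output_1_6",
      "arg": "0"
    }
  ],
  "name": "fig4a"
}
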