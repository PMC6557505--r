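{
  "patches": [
    {
      "id": "dark_skin",
      "rect": [4, 98, 12, 106],
      "ref": [0.45098039, 0.32156863, 0.26666667]
    },
    {
      "id": "light_skin",
      "rect": [14, 98, 22, 106],
      "ref": [0.76078431, 0.58823529, 0.50980392]
    },
    {
      "id": "blue_sky",
      "rect": [24, 98, 32, 106],
      "ref": [0.38431373, 0.47843137, 0.61568627]
    },
    {
      "id": "foliage",
      "rect": [34, 98, 42, 106],
      "ref": [0.34117647, 0.42352941, 0.2627451]
    },
    {
      "id": "blue_flower",
      "rect": [44, 98, 52, 106],
      "ref": [0.52156863, 0.50196078, 0.69411765]
    },
    {
      "id": "bluish_green",
      "rect": [54, 98, 62, 106],
      "ref": [0.40392157, 0.74117647, 0.66666667]
    },
    {
      "id": "orange",
      "rect": [64, 98, 72, 106],
      "ref": [0.83921569, 0.49411765, 0.17254902]
    },
    {
      "id": "purplish_blue",
      "rect": [74, 98, 82, 106],
      "ref": [0.31372549, 0.35686275, 0.65098039]
    },
    {
      "id": "moderate_red",
      "rect": [84, 98, 92, 106],
      "ref": [0.75686275, 0.35294118, 0.38823529]
    },
    {
      "id": "purple",
      "rect": [94, 98, 102, 106],
      "ref": [0.36862745, 0.23529412, 0.42352941]
    },
    {
      "id": "yellow_green",
      "rect": [104, 98, 112, 106],
      "ref": [0.61568627, 0.7372549, 0.25098039]
    },
    {
      "id": "orange_yellow",
      "rect": [114, 98, 122, 106],
      "ref": [0.87843137, 0.63921569, 0.18039216]
    },
    {
      "id": "blue",
      "rect": [4, 108, 12, 116],
      "ref": [0.21960784, 0.23921569, 0.58823529]
    },
    {
      "id": "green",
      "rect": [14, 108, 22, 116],
      "ref": [0.2745098, 0.58039216, 0.28627451]
    },
    {
      "id": "red",
      "rect": [24, 108, 32, 116],
      "ref": [0.68627451, 0.21176471, 0.23529412]
    },
    {
      "id": "yellow",
      "rect": [34, 108, 42, 116],
      "ref": [0.90588235, 0.78039216, 0.12156863]
    },
    {
      "id": "magenta",
      "rect": [44, 108, 52, 116],
      "ref": [0.73333333, 0.3372549, 0.58431373]
    },
    {
      "id": "cyan",
      "rect": [54, 108, 62, 116],
      "ref": [0.03137255, 0.52156863, 0.63137255]
    },
    {
      "id": "white",
      "rect": [64, 108, 72, 116],
      "ref": [0.95294118, 0.95294118, 0.94901961]
    },
    {
      "id": "neutral_8",
      "rect": [74, 108, 82, 116],
      "ref": [0.78431373, 0.78431373, 0.78431373]
    },
    {
      "id": "neutral_65",
      "rect": [84, 108, 92, 116],
      "ref": [0.62745098, 0.62745098, 0.62745098]
    },
    {
      "id": "neutral_5",
      "rect": [94, 108, 102, 116],
      "ref": [0.47843137, 0.47843137, 0.4745098]
    },
    {
      "id": "neutral_35",
      "rect": [104, 108, 112, 116],
      "ref": [0.33333333, 0.33333333, 0.33333333]
    },
    {
      "id": "black",
      "rect": [114, 108, 122, 116],
      "ref": [0.20392157, 0.20392157, 0.20392157]
    }
  ]
}
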