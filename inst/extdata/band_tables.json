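{
  "version": 1,
  "comment": "Band definitions per setup: centers (nm), FWHM (nm), sensor_index = position of the band in the mosaic period cell (row-major, 0-based) or wheel slot. Bands listed sorted by center wavelength; sensor numeration does not follow the sorted order for the mosaic cameras.",
  "setups": {
    "filter_wheel": {
      "pattern": 1,
      "bands": [
        {"center_nm": 400, "fwhm_nm": 10, "sensor_index": 0},
        {"center_nm": 420, "fwhm_nm": 10, "sensor_index": 1},
        {"center_nm": 440, "fwhm_nm": 10, "sensor_index": 2},
        {"center_nm": 460, "fwhm_nm": 10, "sensor_index": 3},
        {"center_nm": 480, "fwhm_nm": 10, "sensor_index": 4},
        {"center_nm": 500, "fwhm_nm": 10, "sensor_index": 5},
        {"center_nm": 520, "fwhm_nm": 10, "sensor_index": 6},
        {"center_nm": 540, "fwhm_nm": 10, "sensor_index": 7},
        {"center_nm": 560, "fwhm_nm": 10, "sensor_index": 8},
        {"center_nm": 580, "fwhm_nm": 10, "sensor_index": 9},
        {"center_nm": 600, "fwhm_nm": 10, "sensor_index": 10},
        {"center_nm": 620, "fwhm_nm": 10, "sensor_index": 11},
        {"center_nm": 640, "fwhm_nm": 10, "sensor_index": 12},
        {"center_nm": 660, "fwhm_nm": 10, "sensor_index": 13},
        {"center_nm": 680, "fwhm_nm": 10, "sensor_index": 14},
        {"center_nm": 700, "fwhm_nm": 10, "sensor_index": 15},
        {"center_nm": 750, "fwhm_nm": 25, "sensor_index": 16},
        {"center_nm": 800, "fwhm_nm": 25, "sensor_index": 17},
        {"center_nm": 850, "fwhm_nm": 25, "sensor_index": 18}
      ]
    },
    "cam4x4": {
      "pattern": 4,
      "bands": [
        {"center_nm": 463, "fwhm_nm": 10.8, "sensor_index": 5},
        {"center_nm": 471, "fwhm_nm": 15.5, "sensor_index": 11},
        {"center_nm": 478, "fwhm_nm": 20.2, "sensor_index": 0},
        {"center_nm": 489, "fwhm_nm": 10.8, "sensor_index": 14},
        {"center_nm": 490, "fwhm_nm": 12.1, "sensor_index": 3},
        {"center_nm": 504, "fwhm_nm": 10.8, "sensor_index": 8},
        {"center_nm": 518, "fwhm_nm": 9.4, "sensor_index": 13},
        {"center_nm": 531, "fwhm_nm": 7.4, "sensor_index": 2},
        {"center_nm": 543, "fwhm_nm": 7.4, "sensor_index": 7},
        {"center_nm": 567, "fwhm_nm": 7.4, "sensor_index": 12},
        {"center_nm": 580, "fwhm_nm": 7.4, "sensor_index": 1},
        {"center_nm": 592, "fwhm_nm": 7.4, "sensor_index": 6},
        {"center_nm": 603, "fwhm_nm": 10.8, "sensor_index": 10},
        {"center_nm": 616, "fwhm_nm": 13.4, "sensor_index": 4},
        {"center_nm": 626, "fwhm_nm": 15.5, "sensor_index": 15},
        {"center_nm": 638, "fwhm_nm": 15.5, "sensor_index": 9}
      ]
    },
    "cam5x5": {
      "pattern": 5,
      "bands": [
        {"center_nm": 693, "fwhm_nm": 4.0, "sensor_index": 7},
        {"center_nm": 707, "fwhm_nm": 4.4, "sensor_index": 19},
        {"center_nm": 732, "fwhm_nm": 5.1, "sensor_index": 2},
        {"center_nm": 746, "fwhm_nm": 4.7, "sensor_index": 24},
        {"center_nm": 758, "fwhm_nm": 7.1, "sensor_index": 11},
        {"center_nm": 772, "fwhm_nm": 6.8, "sensor_index": 0},
        {"center_nm": 784, "fwhm_nm": 6.8, "sensor_index": 16},
        {"center_nm": 798, "fwhm_nm": 8.5, "sensor_index": 9},
        {"center_nm": 809, "fwhm_nm": 6.8, "sensor_index": 22},
        {"center_nm": 821, "fwhm_nm": 7.1, "sensor_index": 5},
        {"center_nm": 839, "fwhm_nm": 10.1, "sensor_index": 13},
        {"center_nm": 851, "fwhm_nm": 8.1, "sensor_index": 1},
        {"center_nm": 861, "fwhm_nm": 8.5, "sensor_index": 18},
        {"center_nm": 872, "fwhm_nm": 8.8, "sensor_index": 6},
        {"center_nm": 881, "fwhm_nm": 10.9, "sensor_index": 21},
        {"center_nm": 891, "fwhm_nm": 12.2, "sensor_index": 10},
        {"center_nm": 900, "fwhm_nm": 15.0, "sensor_index": 3},
        {"center_nm": 910, "fwhm_nm": 12.9, "sensor_index": 23},
        {"center_nm": 924, "fwhm_nm": 15.3, "sensor_index": 8},
        {"center_nm": 932, "fwhm_nm": 14.2, "sensor_index": 15},
        {"center_nm": 940, "fwhm_nm": 18.7, "sensor_index": 12},
        {"center_nm": 948, "fwhm_nm": 19.4, "sensor_index": 4},
        {"center_nm": 955, "fwhm_nm": 25.0, "sensor_index": 20},
        {"center_nm": 961, "fwhm_nm": 17.7, "sensor_index": 14},
        {"center_nm": 966, "fwhm_nm": 15.3, "sensor_index": 17}
      ]
    }
  }
}
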