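map,zone,noncrop_noncrop,noncrop_crop,crop_noncrop,crop_crop,n_noncrop,n_crop,area_total_km2,stated_overall
per_pixel,Zone 1,64.2,9.0,7.7,19.1,138,226,57017,83.3
per_pixel,Zone 2,73.9,6.7,6.8,12.6,169,247,80656,86.5
per_pixel,Zone 3,89.6,4.8,1.6,4.0,177,98,77745,93.6
per_pixel,Zone 4,80.7,5.3,5.7,8.4,65,87,30672,89.1
per_pixel,Ghana,77.2,6.7,5.3,10.8,549,658,248343,88.0
segmentation,Zone 1,57.6,4.2,14.4,23.8,88,276,56795,81.4
segmentation,Zone 2,70.4,3.7,11.2,14.8,121,295,80483,85.2
segmentation,Zone 3,86.6,3.0,4.3,6.1,148,127,78862,92.6
segmentation,Zone 4,75.3,3.4,10.4,10.8,46,106,31158,86.1
segmentation,Ghana,73.2,3.6,9.7,13.5,403,804,248343,86.7
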