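pc,sd_offset,dimension,value,measurement_error
1,3,pedicle_width,5.9,0.2
1,2,pedicle_width,5.8,0.2
1,1,pedicle_width,5.7,0.2
1,0,pedicle_width,5.6,0.2
1,-1,pedicle_width,5.5,0.2
1,-2,pedicle_width,5.4,0.2
1,-3,pedicle_width,5.4,0.2
1,3,pedicle_height,11.0,0.2
1,2,pedicle_height,10.9,0.2
1,1,pedicle_height,10.7,0.2
1,0,pedicle_height,10.5,0.2
1,-1,pedicle_height,10.5,0.2
1,-2,pedicle_height,10.5,0.2
1,-3,pedicle_height,10.3,0.2
1,3,transverse_angle,12.4,0.5
1,2,transverse_angle,11.1,0.5
1,1,transverse_angle,9.6,0.5
1,0,transverse_angle,8.8,0.5
1,-1,transverse_angle,5.7,0.5
1,-2,transverse_angle,4.9,0.5
1,-3,transverse_angle,4.8,0.5
1,3,sagittal_angle,16.5,0.5
1,2,sagittal_angle,15.3,0.5
1,1,sagittal_angle,13.9,0.5
1,0,sagittal_angle,14.2,0.5
1,-1,sagittal_angle,15.5,0.5
1,-2,sagittal_angle,15.8,0.5
1,-3,sagittal_angle,16.1,0.5
2,3,pedicle_width,5.1,0.2
2,2,pedicle_width,5.4,0.2
2,1,pedicle_width,5.5,0.2
2,0,pedicle_width,5.6,0.2
2,-1,pedicle_width,5.7,0.2
2,-2,pedicle_width,5.9,0.2
2,-3,pedicle_width,6.0,0.2
2,3,pedicle_height,9.4,0.2
2,2,pedicle_height,9.7,0.2
2,1,pedicle_height,10.1,0.2
2,0,pedicle_height,10.5,0.2
2,-1,pedicle_height,10.8,0.2
2,-2,pedicle_height,11.3,0.2
2,-3,pedicle_height,11.5,0.2
2,3,transverse_angle,3.5,0.5
2,2,transverse_angle,5.8,0.5
2,1,transverse_angle,10.4,0.5
2,0,transverse_angle,8.8,0.5
2,-1,transverse_angle,8.2,0.5
2,-2,transverse_angle,10.9,0.5
2,-3,transverse_angle,11.0,0.5
2,3,sagittal_angle,15.8,0.5
2,2,sagittal_angle,17.7,0.5
2,1,sagittal_angle,18.4,0.5
2,0,sagittal_angle,14.2,0.5
2,-1,sagittal_angle,14.8,0.5
2,-2,sagittal_angle,14.0,0.5
2,-3,sagittal_angle,14.8,0.5
3,3,pedicle_width,6.2,0.2
3,2,pedicle_width,5.9,0.2
3,1,pedicle_width,5.8,0.2
3,0,pedicle_width,5.6,0.2
3,-1,pedicle_width,5.3,0.2
3,-2,pedicle_width,5.1,0.2
3,-3,pedicle_width,4.7,0.2
3,3,pedicle_height,11.5,0.2
3,2,pedicle_height,11.4,0.2
3,1,pedicle_height,10.8,0.2
3,0,pedicle_height,10.5,0.2
3,-1,pedicle_height,10.0,0.2
3,-2,pedicle_height,9.2,0.2
3,-3,pedicle_height,9.0,0.2
3,3,transverse_angle,7.1,0.5
3,2,transverse_angle,8.1,0.5
3,1,transverse_angle,9.8,0.5
3,0,transverse_angle,8.8,0.5
3,-1,transverse_angle,7.5,0.5
3,-2,transverse_angle,8.8,0.5
3,-3,transverse_angle,6.8,0.5
3,3,sagittal_angle,13.5,0.5
3,2,sagittal_angle,16.8,0.5
3,1,sagittal_angle,15.1,0.5
3,0,sagittal_angle,14.2,0.5
3,-1,sagittal_angle,17.1,0.5
3,-2,sagittal_angle,19.6,0.5
3,-3,sagittal_angle,21.2,0.5
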