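date,lat,lon,sunrise_utc,sunset_utc
2018-03-20,54.1821,7.8925,2018-03-20T05:31:32Z,2018-03-20T17:41:20Z
2018-11-06,-16.5415,-18.4093,2018-11-06T06:34:15Z,2018-11-06T19:20:23Z
2018-02-16,19.5021,-116.7794,2018-02-16T14:15:20Z,2018-02-16T01:46:47Z
2018-07-29,-21.2614,-88.4948,2018-07-29T12:27:06Z,2018-07-29T23:34:00Z
2018-10-19,31.4532,90.3279,2018-10-19T00:04:25Z,2018-10-19T11:22:31Z
2018-02-14,-7.5267,-135.532,2018-02-14T15:06:05Z,2018-02-14T03:26:36Z
2018-10-02,18.3729,160.4403,2018-10-02T19:09:12Z,2018-10-02T07:06:14Z
2018-09-06,22.2237,17.4984,2018-09-06T04:34:26Z,2018-09-06T17:02:03Z
2018-11-07,-21.8775,-158.3257,2018-11-07T15:46:14Z,2018-11-07T04:47:22Z
2018-08-01,30.3582,108.5982,2018-08-01T22:04:31Z,2018-08-01T11:39:38Z
2018-03-23,-9.5275,160.214,2018-03-23T19:23:14Z,2018-03-23T07:28:15Z
2018-10-26,-14.5147,-78.8069,2018-10-26T10:42:39Z,2018-10-26T23:15:48Z
2018-11-28,-53.3384,-94.5943,2018-11-28T09:53:02Z,2018-11-28T02:19:00Z
2018-10-17,-38.7114,-173.0986,2018-10-17T16:43:02Z,2018-10-17T05:51:53Z
2018-11-10,-18.4375,20.0406,2018-11-10T03:56:37Z,2018-11-10T16:51:00Z
2018-12-04,48.7283,-112.2595,2018-12-04T15:04:47Z,2018-12-04T23:33:39Z
2018-12-05,5.012,66.7304,2018-12-05T01:28:20Z,2018-12-05T13:18:50Z
2018-12-04,19.6884,121.2259,2018-12-04T22:15:35Z,2018-12-04T09:15:14Z
2018-02-25,21.7114,-49.8898,2018-02-25T09:43:42Z,2018-02-25T21:21:45Z
2018-10-20,55.2215,-87.5427,2018-10-20T12:30:34Z,2018-10-20T22:38:17Z
2018-03-25,43.5075,106.2864,2018-03-25T22:48:25Z,2018-03-25T11:12:21Z
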